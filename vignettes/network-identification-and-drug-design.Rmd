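---
title: "From expression data to drug combinations: models and methods in gwgenr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From expression data to drug combinations: models and methods in gwgenr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gwgenr)
```

# Overview

`gwgenr` implements a systems-biology pipeline for network-based drug
design. It takes (i) a *candidate* genetic/epigenetic network — a Boolean
edge set of possible protein–protein interactions (PPIs) and
TF/lncRNA/miRNA regulations, typically assembled from interaction
databases — and (ii) an expression matrix over the same nodes, and
produces, in order:

1. the *identified* (real) network: candidate edges whose interaction or
   regulation abilities survive constrained least-squares fitting and
   AIC-based order detection (false positives are pruned);
2. a *core* network: the nodes with the largest 2-norm projections onto
   the principal singular structure of the combined parameter matrix
   (principal network projection, PNP);
3. a drug–target interaction (DTI) classifier — a feedforward network
   over concatenated drug/target descriptor vectors — used to nominate
   candidate drugs per target;
4. a minimal multi-target drug combination satisfying regulation-ability,
   sensitivity and toxicity specifications.

A seeded synthetic-data module generates all inputs with known ground
truth, so every stage is testable without any database download.

# The node models

Expression of each node is described by a static model over its network
neighbours, per sample $n = 1, \dots, N$.

**Proteins.** The $s$-th protein follows a bilinear interaction model
$$
p_s[n] \;=\; \sum_{w} \tau_{sw}\, p_s[n]\, p_w[n] \;+\; \zeta_s \;+\; \psi_s[n],
$$
where $\tau_{sw}$ is the interaction ability with interactor $w$,
$\zeta_s$ a basal level (unmodelled modification effects), and
$\psi_s[n]$ Gaussian noise.

**Genes (and, with their own symbols, lncRNAs and miRNAs).** The $t$-th
gene follows
$$
g_t[n] \;=\; \sum_f \alpha_{tf}\, t_f[n] \;+\; \sum_g \beta_{tg}\, i_g[n]
\;-\; \sum_h \delta_{th}\, m_h[n]\, g_t[n] \;+\; \zeta_t \;+\; \psi_t[n],
$$
with TFs and lncRNAs acting additively (free-signed $\alpha, \beta$) and
miRNAs repressing multiplicatively with abilities $\delta_{th} \ge 0$.
lncRNA and miRNA targets use the same structural form; the package keeps
their coefficients under the same regression machinery.

# System identification and order detection

Each node's model is rewritten as a linear regression: one column per
candidate regulator (bilinear columns $p_s p_w$ for PPIs, raw regulator
expression for TFs/lncRNAs, product columns $m_h g_t$ for miRNAs) plus an
all-ones basal column. miRNA-class coefficients are constrained to be
nonpositive; `solve_constrained_lsq()` enforces this with a
Lawson–Hanson-style active-set iteration (validated in the test suite
against a projected-gradient oracle). To avoid overfitting, a node's
regressor count is capped at $\lfloor N/2 \rfloor - 1$; over-connected
nodes are pre-truncated to the candidates with the largest absolute
Pearson correlation with the target — a deterministic, cheap rule that
preserves strong signals.

The retained order is chosen by minimizing
$$
\mathrm{AIC}(k) \;=\; \log \hat\Phi^2 \;+\; \frac{2(k+1)}{N},
\qquad \hat\Phi = \frac{\mathrm{SSE}}{N},
$$
with $\hat\Phi$ floored at $10^{-12}$ so noiseless exact fits stay
finite. Because the exhaustive argmin over regulator subsets is
exponential, `detect_order()` walks a greedy backward-elimination path —
drop the smallest-magnitude estimate, refit, record the AIC at every
order down to basal-only — and returns the path minimum (ties go to the
smaller order, for parsimony). `detect_order_exhaustive()` provides the
all-subsets oracle; on seeded random problems with up to eight candidates
the greedy path attains the exhaustive minimum in well over 95% of
instances.

Two properties of this criterion are worth knowing. First, written on
$\log \hat\Phi^2 = 2 \log \hat\Phi$, its per-regressor penalty is half
that of the classical form $N \log \hat\Phi + 2(k+1)$, so it prunes
conservatively: weakly correlated decoys are sometimes retained. The
classical form is available via `variant = "textbook"` for sensitivity
checks. Second, because the greedy path can miss the exhaustive optimum
on a small fraction of nodes, whole-network summaries (e.g.
retained-edge F1 against a synthetic truth) may differ from the
exhaustive oracle's by a few thousandths on some seeds; the per-problem
agreement rate is the stable guarantee.

PPIs are estimated once per direction (the bilinear term sits in the
target node's own regression); symmetry $\tau_{sw} = \tau_{ws}$ is not
enforced, and comparisons against a planted truth treat PPI edges as
unordered pairs.

# Principal network projection

All estimated parameters are assembled into a combined matrix $W$ whose
rows are the network nodes (proteins, then genes, lncRNAs, miRNAs) and
whose columns are the regulator nodes (TFs, then lncRNAs, then miRNAs);
cells without a retained edge are exactly zero. A TF appears both as a
row (it is a protein) and as a column (it is a regulator), linked by
shared identifier; a PPI whose partner is not a TF has no column to
occupy and therefore contributes no cell (it remains part of the
identified network). From the SVD $W = U \Sigma V^T$:

* the *eigen expression fraction* of singular value $x$ is
  $E_x = \Sigma_x^2 / \sum_y \Sigma_y^2$ (they sum to one);
* $X$ is the smallest count with $\sum_{x \le X} E_x \ge$ the energy
  threshold (default 0.85, applied literally as a $\ge$ comparison);
* each node's projection norm is
  $Q(a) = \sqrt{\sum_{b \le X} (w_{a,:} \cdot v_{:,b})^2}$.

Nodes are ranked by $Q$ (ties broken lexicographically by node id, for
determinism); the core network is the subnetwork induced by the top $K$
nodes. $K$ defaults to 6000 — effectively "all nodes" at desk scale,
where synthetic networks have a hundred or so — and is a parameter
because the interesting choices are much smaller there. Nodes with
$Q < 10^{-12}$ are flagged as insignificant (essentially independent of
the principal structure) but never silently dropped.

# The drug–target interaction classifier

Drug–target pairs are concatenated descriptor vectors with binary labels
(1 = proven interaction). The training protocol is: random down-sampling
of the majority class to exact balance; a 3:1 train/test split;
per-feature standardization and a PCA projection, both fitted on the
training partition only and frozen for held-out data (the test suite
asserts this no-leakage contract); then a feedforward network — ReLU
hidden layers, a logistic output unit, mean binary cross-entropy loss —
trained by plain mini-batch gradient descent
$\theta \leftarrow \theta - \eta \nabla L(\theta)$, with inverted dropout
on each hidden layer during training and early stopping on validation
loss (patience 10, best weights restored). Defaults: $\eta = 0.001$, 100
epochs, batch size 100, dropout 0.2, hidden widths 512/256/128/64,
five-fold cross-validation. Dropout rate and the early-stopping rule are
conventional choices where the protocol leaves them open.

The reference widths and learning rate are tuned to database-scale
training sets (tens of thousands of pairs, where each epoch contains
hundreds of mini-batch updates). Desk-scale datasets of a few hundred
samples provide very few updates per epoch, so the package's own tests
and the bundled pipeline use narrower layers (8–64 units) and, for the
smallest property tests, a larger step size with more epochs; the
architecture and update rule are unchanged. Evaluation reports the ROC
curve by threshold sweep, the AUC by the trapezoid rule (equal to
pairwise concordance, which the tests verify exhaustively on small
cases), and confusion counts at the 0.5 threshold.

# Drug design specifications and combination selection

For each disease target (a biomarker with a dysregulation direction), a
candidate drug passes the specification filter if

* its regulation ability *opposes* the dysregulation (strictly negative
  score for an upregulated biomarker, strictly positive for a
  downregulated one — a zero-effect drug cannot restore expression);
* its sensitivity is close to zero, quantified as
  $|\text{sensitivity}| \le s_{\max}$ with default $s_{\max} = 3.0$
  (log-fold viability units): the loosest round bound consistent with
  the reference selections, and configurable;
* survivors are ranked by descending LC50 (log mol/kg) — higher LC50,
  lower toxicity.

`select_combination()` enumerates all drug subsets up to the smallest
size that covers every target (candidate pools are five drugs per
target, so enumeration is exact) and picks the winner by ordered
criteria: fewest drugs; largest minimum LC50 across the selected drugs;
most drug–target coverage links; largest per-target best absolute
regulation; lexicographic names. The full comparison trace is returned
so every tie-break is auditable. On the bundled drug-property tables
this procedure selects Embelin + Obatoclax for the muscle-invasive
bladder cancer target set {NFKB1, MYC, LEF1} and Obatoclax + Entinostat
+ Imiquimod for the advanced bladder cancer set {LEF1, MYC, FOXO1,
NOTCH1}.

# The synthetic-data generator

`generate_candidate_network()` plants a ground-truth network: each
kind-compatible regulator slot carries a true edge with the configured
density, and the candidate network adds a configured multiple of
kind-compatible decoy edges (uniformly sampled, disjoint from the
truth) — the simplest null for false-positive pruning. Parameter
magnitudes are uniform on `param_range` (default [0.3, 1]); signs are
random for PPI and gene-level regulation, positive for regulation of
nonnegative ncRNA targets, and miRNA repression abilities are positive
by construction.

`simulate_expression()` produces data satisfying every node equation
*exactly*, without fixed-point iteration, by solving each equation for
its target: $p = (\zeta + \psi) / (1 - \sum \tau p_w)$ for proteins and
$g = (\sum \alpha t + \sum \beta i + \zeta + \psi) / (1 + \sum \delta m)$
for regulated genes/ncRNAs. To make a sequential walk exact, the truth is
generated as a directed acyclic structure: a PPI's bilinear term enters
the higher-ordered endpoint's equation, and ncRNA-to-ncRNA regulations
run forward along a fixed node order (the candidate network still offers
both PPI directions to the identifier, so the unplanted direction acts as
a decoy). Across-sample variation enters through *exogenous* nodes —
regulator-capable nodes with no incoming true edge — drawn i.i.d.
uniform on `regulator_range` (default [0.5, 2], positive so miRNA terms
stay nonnegative and solved-form denominators stay at least one).
Numerical guards: a protein's solved-form denominator is kept at
$|1 - \sum \tau p_w| \ge 0.2$ by halving that node's $\tau$ draws (at
most 100 times, then an error), and ncRNA noise draws are redrawn if they
would push the value negative. The realized noise matrix and the truth
actually used are attached to the dataset for residual bookkeeping.

What the generator does *not* emulate: microarray platform artifacts,
probe-level noise structure, normalization effects, correlated
measurement error, or realistic degree distributions. Passing tests
therefore certify the estimation and selection machinery under the
stated statistical model, not performance on real microarray data.

`generate_dti_dataset()` draws two unit-covariance Gaussian classes in
feature space whose means are `class_separation` apart, giving a
closed-form Bayes AUC of $\Phi(\text{separation}/\sqrt 2)$ against which
classifier behaviour is checked.

# Reference scenario and problem sizes

The package's reference scenario — used by its own regression checks and
the `scripts/acceptance.R` report — is 30 proteins (6 of them TFs), 40
genes, 6 lncRNAs and 8 miRNAs over 200 samples, edge density 0.1, one
decoy per true edge, noise standard deviation 0.05. These sizes keep
every candidate node's regression well-posed under the
$\lfloor N/2\rfloor - 1$ cap, keep the all-subsets oracle affordable, and
exercise all four node classes and all edge types. Pipeline and training
tests use smaller variants of the same structure.

# Interfaces

All tabular I/O is UTF-8 TSV (expression matrices with a node-kind
sidecar; edge lists with `source`, `target`, `edge_type` and optional
`parameter`; drug-property and target-spec tables), with floats at nine
significant digits for stable round trips. `run_pipeline()` executes
simulate → identify → project → train → design from one seeded
configuration and writes a manifest recording versions, parameters and
headline outputs; a single seed fixes every stochastic choice in every
stage. The package's interface is its R functions; the pipeline runner
and the acceptance script are thin wrappers over them, so no separate
shell command layer is shipped.

# Known limitations

* The printed-form AIC prunes conservatively; identified networks retain
  some decoys at realistic noise (precision well below recall on the
  synthetic scenario). The textbook variant is stricter.
* Greedy backward elimination is not guaranteed optimal; see the
  agreement-rate discussion above.
* PPI orientation is not identified; only unordered interaction pairs
  are meaningful.
* PPIs with non-TF partners do not enter the combined projection matrix,
  so a node connected only through such edges can rank as insignificant
  despite genuine interactions.
* The MLP is plain gradient descent by design fidelity; it needs
  learning-rate/epoch adjustment at very small sample sizes (no
  adaptive optimizer by default).
* The combination selector's tie-break ladder is a deterministic
  formalization of "considering the pharmacological properties"; other
  defensible ladders exist, which is why the full trace is emitted.
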