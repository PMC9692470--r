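#' Simulation configuration for synthetic network scenarios
#'
#' Bundles the knobs of the synthetic-data generator: node counts per class,
#' sample count, true-edge density, decoy load, noise level and parameter
#' ranges. The defaults define the package's reference scenario: a small
#' genetic/epigenetic network (30 proteins of which 6 are transcription
#' factors, 40 genes, 6 lncRNAs, 8 miRNAs) observed over 200 samples with
#' edge density 0.1, one decoy edge per true edge and Gaussian noise of
#' standard deviation 0.05.
#'
#' @param n_proteins,n_genes,n_lncrnas,n_mirnas Node counts per class.
#' @param n_tfs Number of proteins additionally acting as transcription
#'   factors (the first `n_tfs` proteins).
#' @param n_samples Number of samples (patients) N.
#' @param true_edge_density Fraction of kind-compatible regulator slots that
#'   carry a true edge, in `[0, 1]`.
#' @param decoy_edge_multiplier Decoy (false-positive) edges added per true
#'   edge when building the candidate network.
#' @param noise_sd Standard deviation of the additive Gaussian noise term in
#'   every node equation.
#' @param basal_range Interval for basal expression levels.
#' @param param_range Interval for interaction/regulation magnitudes.
#' @param regulator_range Interval for the per-sample i.i.d. uniform
#'   expression of exogenous regulator nodes (nodes without incoming true
#'   edges); positive so miRNA repression terms stay nonnegative.
#' @param seed Integer seed fixing every random draw.
#' @return An object of class `gw_sim_config` (a validated list).
#' @export
simulation_config <- function(n_proteins = 30L, n_genes = 40L,
                              n_lncrnas = 6L, n_mirnas = 8L, n_tfs = 6L,
                              n_samples = 200L,
                              true_edge_density = 0.1,
                              decoy_edge_multiplier = 1,
                              noise_sd = 0.05,
                              basal_range = c(0.5, 2),
                              param_range = c(0.3, 1),
                              regulator_range = c(0.5, 2),
                              seed = 1L) {
  cfg <- list(
    n_proteins = check_count(n_proteins, "n_proteins"),
    n_genes = check_count(n_genes, "n_genes"),
    n_lncrnas = check_count(n_lncrnas, "n_lncrnas"),
    n_mirnas = check_count(n_mirnas, "n_mirnas"),
    n_tfs = check_count(n_tfs, "n_tfs"),
    n_samples = check_count(n_samples, "n_samples"),
    true_edge_density = check_fraction(true_edge_density, "true_edge_density"),
    decoy_edge_multiplier = as.numeric(decoy_edge_multiplier),
    noise_sd = as.numeric(noise_sd),
    basal_range = as.numeric(basal_range),
    param_range = as.numeric(param_range),
    regulator_range = as.numeric(regulator_range),
    seed = check_count(seed, "seed", min = 0L)
  )
  if (cfg$n_tfs > cfg$n_proteins) stop_gw("n_tfs must not exceed n_proteins")
  if (cfg$decoy_edge_multiplier < 0) stop_gw("decoy_edge_multiplier must be >= 0")
  if (cfg$noise_sd < 0) stop_gw("noise_sd must be >= 0")
  if (length(cfg$basal_range) != 2L || diff(cfg$basal_range) < 0) {
    stop_gw("basal_range must be an increasing interval")
  }
  if (length(cfg$param_range) != 2L || cfg$param_range[1] <= 0 ||
      diff(cfg$param_range) < 0) {
    stop_gw("param_range must be a positive increasing interval")
  }
  if (length(cfg$regulator_range) != 2L || cfg$regulator_range[1] < 0 ||
      diff(cfg$regulator_range) < 0) {
    stop_gw("regulator_range must be a nonnegative increasing interval")
  }
  structure(cfg, class = "gw_sim_config")
}

# Node id tables for a configuration. Proteins come first (TF-flagged ones
# leading), then genes, then ncRNAs in the fixed generation order
# (miRNAs before lncRNAs) used to keep regulations acyclic.
sim_nodes <- function(cfg) {
  pad <- function(prefix, n) sprintf("%s%0*d", prefix, nchar(n), seq_len(n))
  proteins <- pad("P", cfg$n_proteins)
  genes <- pad("G", cfg$n_genes)
  lncrnas <- pad("L", cfg$n_lncrnas)
  mirnas <- pad("M", cfg$n_mirnas)
  kinds <- c(
    stats::setNames(rep("protein", cfg$n_proteins), proteins),
    stats::setNames(rep("gene", cfg$n_genes), genes),
    stats::setNames(rep("lncrna", cfg$n_lncrnas), lncrnas),
    stats::setNames(rep("mirna", cfg$n_mirnas), mirnas)
  )
  kinds[proteins[seq_len(cfg$n_tfs)]] <- "tf"
  list(
    proteins = proteins, genes = genes, lncrnas = lncrnas, mirnas = mirnas,
    tfs = proteins[seq_len(cfg$n_tfs)],
    nc_order = c(mirnas, lncrnas),
    kinds = kinds
  )
}

# All kind-compatible regulator slots, as a data.frame of
# (source, target, edge_type). `dag_only` restricts ncRNA->ncRNA slots to
# the acyclic forward direction used for true edges.
sim_slots <- function(nodes, dag_only) {
  slots <- list()
  np <- length(nodes$proteins)
  if (np >= 2) {
    pairs <- utils::combn(nodes$proteins, 2)
    slots$pp <- data.frame(
      source = pairs[1, ], target = pairs[2, ], edge_type = "pp",
      stringsAsFactors = FALSE
    )
  }
  reg_targets <- c(nodes$genes, nodes$nc_order)
  nc_pos <- stats::setNames(seq_along(nodes$nc_order), nodes$nc_order)
  add_reg <- function(sources, type) {
    if (length(sources) == 0 || length(reg_targets) == 0) return(NULL)
    df <- expand.grid(
      source = sources, target = reg_targets,
      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
    )
    df$edge_type <- type
    df <- df[df$source != df$target, , drop = FALSE]
    if (dag_only && type %in% c("lnc_reg", "mir_reg")) {
      src_pos <- nc_pos[df$source]
      tgt_pos <- nc_pos[df$target]
      keep <- is.na(tgt_pos) | (!is.na(src_pos) & src_pos < tgt_pos)
      df <- df[keep, , drop = FALSE]
    }
    df[, c("source", "target", "edge_type")]
  }
  slots$tf <- add_reg(nodes$tfs, "tf_reg")
  slots$lnc <- add_reg(nodes$lncrnas, "lnc_reg")
  slots$mir <- add_reg(nodes$mirnas, "mir_reg")
  out <- do.call(rbind, slots)
  rownames(out) <- NULL
  out
}

slot_key <- function(df) paste(df$source, df$target, df$edge_type)

#' Generate a candidate network with a planted ground truth
#'
#' Samples a true network (edges with parameter values, basal levels) and a
#' Boolean candidate network containing the true edges plus kind-compatible
#' decoy edges, emulating a database-derived candidate network whose false
#' positives must later be pruned from expression data.
#'
#' True regulations among non-coding RNAs run only forward along a fixed
#' node order so that expression can be generated exactly from the solved
#' node equations; decoys are unrestricted. Protein-protein interaction
#' parameters are attached to the higher-ordered endpoint, whose equation
#' carries the bilinear term.
#'
#' @param config A [simulation_config()].
#' @return A list with elements `candidate` (class `gw_candidate`: Boolean
#'   typed edge list plus node kinds) and `truth` (class `gw_truth`: typed
#'   edges with parameters, basal levels, node kinds).
#' @export
generate_candidate_network <- function(config) {
  stopifnot(inherits(config, "gw_sim_config"))
  nodes <- sim_nodes(config)
  with_seed(config$seed, {
    true_slots <- sim_slots(nodes, dag_only = TRUE)
    all_slots <- sim_slots(nodes, dag_only = FALSE)
    n_true <- round(config$true_edge_density * nrow(true_slots))
    truth_edges <- if (n_true > 0) {
      true_slots[sort(sample.int(nrow(true_slots), n_true)), , drop = FALSE]
    } else empty_edges(param = FALSE)

    n_decoy <- round(config$decoy_edge_multiplier * nrow(truth_edges))
    pool <- all_slots[!(slot_key(all_slots) %in% slot_key(truth_edges)), ,
                      drop = FALSE]
    if (n_decoy > nrow(pool)) {
      stop_gw(paste0(
        "infeasible configuration: %d decoy edges requested but only %d ",
        "kind-compatible non-true slots exist"), n_decoy, nrow(pool))
    }
    decoys <- if (n_decoy > 0) {
      pool[sort(sample.int(nrow(pool), n_decoy)), , drop = FALSE]
    } else empty_edges(param = FALSE)[, 1:3]

    # parameters: signed magnitudes for PPI and gene-level regulation,
    # positive for regulation of (nonnegative) ncRNA targets, and positive
    # repression magnitudes (stored negative later) for miRNA edges
    n_e <- nrow(truth_edges)
    mag <- stats::runif(n_e, config$param_range[1], config$param_range[2])
    tgt_kind <- nodes$kinds[truth_edges$target]
    sign_free <- truth_edges$edge_type %in% c("pp", "tf_reg", "lnc_reg") &
      tgt_kind %in% c("gene", "protein", "tf")
    sgn <- ifelse(sign_free, sample(c(-1, 1), n_e, replace = TRUE), 1)
    truth_edges$parameter <- mag * sgn

    basal <- stats::runif(length(nodes$kinds),
                          config$basal_range[1], config$basal_range[2])
    names(basal) <- names(nodes$kinds)

    cand_edges <- rbind(truth_edges[, c("source", "target", "edge_type")],
                        decoys[, c("source", "target", "edge_type")])
    cand_edges <- cand_edges[order(cand_edges$edge_type, cand_edges$source,
                                   cand_edges$target), , drop = FALSE]
    rownames(cand_edges) <- NULL
    rownames(truth_edges) <- NULL

    cap <- degree_cap(config$n_samples)
    deg <- table(c(cand_edges$target, cand_edges$source[cand_edges$edge_type == "pp"]))
    if (any(deg > cap)) {
      stop_gw(paste0(
        "infeasible configuration: node '%s' has %d candidate regulators ",
        "but at most %d are identifiable with %d samples"),
        names(deg)[which.max(deg)], max(deg), cap, config$n_samples)
    }

    truth <- structure(
      list(edges = truth_edges, basal = basal, node_kinds = nodes$kinds,
           nodes = nodes, config = config),
      class = "gw_truth"
    )
    candidate <- structure(
      list(edges = cand_edges, node_kinds = nodes$kinds),
      class = "gw_candidate"
    )
    list(candidate = candidate, truth = truth)
  })
}

# edges regulating `node` in a typed edge data.frame; for PPIs the partner
# may sit on either side of the stored pair
incoming_edges <- function(edges, node) {
  pp <- edges[edges$edge_type == "pp" &
                (edges$source == node | edges$target == node), , drop = FALSE]
  if (nrow(pp) > 0) {
    partner <- ifelse(pp$source == node, pp$target, pp$source)
    pp$source <- partner
    pp$target <- node
  }
  reg <- edges[edges$edge_type != "pp" & edges$target == node, , drop = FALSE]
  out <- rbind(pp, reg)
  rownames(out) <- NULL
  out
}

#' Simulate expression data from a ground-truth network
#'
#' Generates a node-by-sample expression matrix that satisfies every node's
#' model equation exactly: proteins follow a bilinear interaction model with
#' a basal level and additive noise, genes and non-coding RNAs follow a
#' regulatory model in which transcription factors and lncRNAs act
#' additively and miRNAs repress multiplicatively with nonnegative
#' abilities. Each node's value is computed from the algebraically solved
#' form of its (implicit) equation, walking nodes in dependency order.
#'
#' Across-sample variation enters through the exogenous nodes: every
#' regulator-capable node without incoming true edges (proteins, lncRNAs,
#' miRNAs) is an expression source drawn i.i.d. uniform on
#' `regulator_range` per sample; regulated nodes are computed from them in
#' dependency order, and unregulated genes are pure basal-plus-noise. For
#' an exogenous node the model equation reduces to basal plus noise, so
#' its realized noise term is recorded as value minus basal — the
#' Gaussian-noise bookkeeping applies to the regulated nodes.
#'
#' A denominator guard keeps the protein equations well conditioned: if any
#' protein's solved-form denominator falls below 0.2 in absolute value for
#' any sample, that protein's interaction parameters are halved and the
#' protein stage rerun (at most 100 times, then an error). ncRNA values are
#' kept nonnegative by redrawing their noise terms when needed. The truth
#' actually used (after any rescaling) and the realized noise matrix are
#' attached as attributes `truth` and `noise` for residual bookkeeping.
#'
#' @param truth A `gw_truth` ground-truth network.
#' @param config The [simulation_config()] that produced it.
#' @return An object of class `gw_expression`: list with `values` (node x
#'   sample matrix), `node_ids`, `node_kinds`, `sample_ids`.
#' @export
simulate_expression <- function(truth, config) {
  stopifnot(inherits(truth, "gw_truth"), inherits(config, "gw_sim_config"))
  nodes <- truth$nodes
  node_ids <- names(truth$node_kinds)
  N <- config$n_samples
  with_seed(config$seed + 1L, {
    psi <- matrix(stats::rnorm(length(node_ids) * N, sd = config$noise_sd),
                  nrow = length(node_ids), dimnames = list(node_ids, NULL))
    values <- matrix(NA_real_, nrow = length(node_ids), ncol = N,
                     dimnames = list(node_ids, NULL))
    edges <- truth$edges

    # exogenous sources: regulator-capable nodes without incoming true
    # edges vary i.i.d. uniform across samples; their realized noise term
    # is value minus basal
    regulated <- unique(c(edges$target[edges$edge_type != "pp"],
                          edges$target[edges$edge_type == "pp"]))
    exogenous <- setdiff(c(nodes$proteins, nodes$nc_order), regulated)
    for (nd in exogenous) {
      values[nd, ] <- stats::runif(N, config$regulator_range[1],
                                   config$regulator_range[2])
      psi[nd, ] <- values[nd, ] - truth$basal[nd]
    }

    # protein stage: p_s = (zeta + psi) / (1 - sum tau * p_w), interactors
    # restricted to lower-ordered proteins so the walk is exact
    for (attempt in seq_len(100L)) {
      ok <- TRUE
      for (s in setdiff(nodes$proteins, exogenous)) {
        inc <- edges[edges$edge_type == "pp" & edges$target == s, , drop = FALSE]
        denom <- rep(1, N)
        if (nrow(inc) > 0) {
          pw <- values[inc$source, , drop = FALSE]
          denom <- 1 - as.numeric(crossprod(inc$parameter, pw))
        }
        if (any(abs(denom) < 0.2)) {
          edges$parameter[edges$edge_type == "pp" & edges$target == s] <-
            inc$parameter * 0.5
          ok <- FALSE
          break
        }
        values[s, ] <- (truth$basal[s] + psi[s, ]) / denom
      }
      if (ok) break
      if (attempt == 100L) {
        stop_gw("protein denominator guard failed after 100 rescaling attempts")
      }
    }

    solve_regulated <- function(node, nonneg) {
      inc <- edges[edges$edge_type != "pp" & edges$target == node, , drop = FALSE]
      add <- inc[inc$edge_type %in% c("tf_reg", "lnc_reg"), , drop = FALSE]
      rep_ <- inc[inc$edge_type == "mir_reg", , drop = FALSE]
      numer_reg <- if (nrow(add) > 0) {
        as.numeric(crossprod(add$parameter, values[add$source, , drop = FALSE]))
      } else rep(0, N)
      denom <- if (nrow(rep_) > 0) {
        1 + as.numeric(crossprod(rep_$parameter, values[rep_$source, , drop = FALSE]))
      } else rep(1, N)
      val <- (numer_reg + truth$basal[node] + psi[node, ]) / denom
      if (nonneg) {
        for (tries in seq_len(100L)) {
          bad <- which(val < 0)
          if (length(bad) == 0) break
          psi[node, bad] <<- stats::rnorm(length(bad), sd = config$noise_sd)
          val[bad] <- (numer_reg[bad] + truth$basal[node] + psi[node, bad]) /
            denom[bad]
          if (tries == 100L && any(val < 0)) {
            stop_gw("could not keep node '%s' nonnegative after 100 noise redraws",
                    node)
          }
        }
      }
      val
    }

    for (nc in setdiff(nodes$nc_order, exogenous)) {
      values[nc, ] <- solve_regulated(nc, nonneg = TRUE)
    }
    for (g in nodes$genes) values[g, ] <- solve_regulated(g, nonneg = FALSE)

    truth_used <- truth
    truth_used$edges <- edges
    structure(
      list(values = values, node_ids = node_ids,
           node_kinds = truth$node_kinds,
           sample_ids = sprintf("S%0*d", nchar(N), seq_len(N))),
      class = "gw_expression",
      noise = psi, truth = truth_used
    )
  })
}

#' Synthetic drug-target interaction dataset configuration
#'
#' @param n_drug_features,n_target_features Numbers of drug and target
#'   features (the concatenated feature vector has their sum as length).
#' @param n_positive,n_negative Class sizes (label 1 = proven interaction,
#'   label 0 = unproven).
#' @param class_separation Euclidean distance between the two class means
#'   (unit-variance Gaussian classes); 0 makes the classes
#'   indistinguishable.
#' @param seed Integer seed.
#' @return An object of class `gw_dti_config`.
#' @export
dti_config <- function(n_drug_features = 20L, n_target_features = 20L,
                       n_positive = 500L, n_negative = 500L,
                       class_separation = 6, seed = 1L) {
  cfg <- list(
    n_drug_features = check_count(n_drug_features, "n_drug_features"),
    n_target_features = check_count(n_target_features, "n_target_features"),
    n_positive = check_count(n_positive, "n_positive"),
    n_negative = check_count(n_negative, "n_negative"),
    class_separation = as.numeric(class_separation),
    seed = check_count(seed, "seed", min = 0L)
  )
  if (cfg$class_separation < 0) stop_gw("class_separation must be >= 0")
  structure(cfg, class = "gw_dti_config")
}

#' Generate a labeled drug-target feature table
#'
#' Draws two Gaussian classes in concatenated drug/target feature space:
#' unproven pairs (label 0) centred at the origin and proven pairs (label 1)
#' centred at a mean vector whose Euclidean norm equals `class_separation`,
#' both with identity covariance. Emulates the separable-but-noisy structure
#' of descriptor-based interaction data with configurable class imbalance.
#'
#' @param config A [dti_config()].
#' @return A data.frame with drug feature columns `d1..dM`, target feature
#'   columns `t1..tN` and a binary `label` column.
#' @export
generate_dti_dataset <- function(config) {
  stopifnot(inherits(config, "gw_dti_config"))
  d <- config$n_drug_features + config$n_target_features
  n <- config$n_positive + config$n_negative
  with_seed(config$seed, {
    x <- matrix(stats::rnorm(n * d), nrow = n)
    labels <- rep(c(1L, 0L), c(config$n_positive, config$n_negative))
    shift <- config$class_separation / sqrt(d)
    x[labels == 1L, ] <- x[labels == 1L, ] + shift
    colnames(x) <- c(sprintf("d%d", seq_len(config$n_drug_features)),
                     sprintf("t%d", seq_len(config$n_target_features)))
    out <- as.data.frame(x)
    out$label <- labels
    out
  })
}
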