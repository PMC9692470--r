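# Shared fixtures and independent oracles for the test suite.

# A tiny scenario used by several files; regenerating is cheap.
tiny_config <- function(seed = 7, ...) {
  simulation_config(n_proteins = 10L, n_tfs = 3L, n_genes = 12L,
                    n_lncrnas = 3L, n_mirnas = 4L, n_samples = 80L,
                    seed = seed, ...)
}

# Overwrite a generated truth's edges/basal with hand-set values, keeping
# the node bookkeeping intact. `edges` must be a data.frame with columns
# source, target, edge_type, parameter.
patch_truth <- function(truth, edges, basal = NULL) {
  truth$edges <- edges
  if (!is.null(basal)) truth$basal[names(basal)] <- basal
  truth
}

# Build a regression problem object directly (bypassing a network), for
# solver- and order-detection-level tests.
make_problem <- function(X, y, constrained, classes = NULL) {
  p <- ncol(X) - 1L
  if (is.null(classes)) classes <- ifelse(constrained, "miRNA", "TF")
  structure(
    list(y = y, X = X,
         labels = paste0("r", seq_len(p)),
         classes = classes,
         edge_types = ifelse(constrained, "mir_reg", "tf_reg"),
         sign_constrained = constrained,
         node_id = "node", node_kind = "gene", truncated = FALSE),
    class = "gw_regression"
  )
}

# Projected-gradient oracle for the sign-constrained least squares:
# minimizes 0.5*||X theta - y||^2 with theta_j <= 0 on constrained
# coordinates by projected gradient descent at the Lipschitz step size.
pg_lsq_oracle <- function(X, y, constrained, iters = 50000L) {
  L <- max(eigen(crossprod(X), symmetric = TRUE, only.values = TRUE)$values)
  theta <- rep(0, ncol(X))
  for (i in seq_len(iters)) {
    grad <- as.numeric(crossprod(X, X %*% theta - y))
    theta <- theta - grad / L
    theta[constrained & theta > 0] <- 0
  }
  theta
}

lsq_objective <- function(X, y, theta) 0.5 * sum((as.numeric(X %*% theta) - y)^2)

# Pairwise-concordance oracle for the AUC: P(score_pos > score_neg) plus
# half the tie probability, enumerated over all positive/negative pairs.
concordance_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}

# Eigen-decomposition-based oracle for the principal network projection:
# right singular vectors from eigen(W'W), energy fractions from its
# eigenvalues, projections entry by entry.
pnp_oracle <- function(M, threshold = 0.85) {
  eg <- eigen(crossprod(M), symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  ex <- ev / sum(ev)
  X <- which(cumsum(ex) >= threshold - 1e-15)[1]
  P <- matrix(0, nrow(M), X)
  for (a in seq_len(nrow(M))) {
    for (b in seq_len(X)) P[a, b] <- sum(M[a, ] * eg$vectors[, b])
  }
  list(ex = ex, X = X, Q = sqrt(rowSums(P^2)))
}

# Wrap a plain matrix as a combined network matrix for projection tests.
as_gw_W <- function(M, kinds = NULL) {
  if (is.null(rownames(M))) rownames(M) <- sprintf("n%02d", seq_len(nrow(M)))
  if (is.null(colnames(M))) colnames(M) <- sprintf("c%02d", seq_len(ncol(M)))
  if (is.null(kinds)) kinds <- stats::setNames(rep("gene", nrow(M)), rownames(M))
  structure(list(values = M, row_kinds = kinds, block_map = NULL),
            class = "gw_W")
}

# Desk-scale end-to-end pipeline configuration.
pipeline_test_config <- function(seed = 3) {
  pipeline_config(
    seed = seed,
    simulation = simulation_config(n_proteins = 12L, n_tfs = 4L,
                                   n_genes = 15L, n_lncrnas = 3L,
                                   n_mirnas = 4L, n_samples = 80L),
    dti_data = dti_config(n_drug_features = 8L, n_target_features = 8L,
                          n_positive = 120L, n_negative = 150L,
                          class_separation = 5),
    training = training_config(hidden_sizes = c(16L, 8L), epochs = 60L,
                               learning_rate = 0.05)
  )
}

# A quickly converging desk-scale training configuration for property
# tests (higher learning rate and epoch count than the reference protocol
# because the toy datasets provide very few mini-batch updates).
fast_train_config <- function(seed = 1L, ...) {
  args <- list(...)
  defaults <- list(hidden_sizes = c(8L), epochs = 150L, learning_rate = 0.05,
                   seed = seed)
  do.call(training_config, utils::modifyList(defaults, args))
}
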