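#' Build the per-node regression problem
#'
#' Rewrites one node's interactive/regulatory model as a linear regression
#' over its candidate regulators. Protein targets get one bilinear column
#' per candidate interactor (target expression times interactor
#' expression); gene, lncRNA and miRNA targets get one column per candidate
#' TF (TF expression), lncRNA (lncRNA expression) and miRNA (miRNA
#' expression times target expression, carrying a nonpositivity constraint
#' on its coefficient). A final all-ones column estimates the basal level.
#'
#' When a node has more candidate regulators than `floor(N/2) - 1` (the
#' overfitting guard: the model order must stay below half the sample
#' count), the candidates are pre-truncated to that cap, keeping the
#' columns with the largest absolute Pearson correlation with the target.
#'
#' @param node Node id present in `data`.
#' @param data A `gw_expression` dataset.
#' @param candidates A `gw_candidate` (or `gw_truth`) network; only edge
#'   structure is used.
#' @return An object of class `gw_regression`: target vector `y`, regressor
#'   matrix `X` (N x (order + 1), last column the basal constant),
#'   `labels`/`classes` describing each regressor column,
#'   `sign_constrained` logical vector (TRUE for miRNA-class columns),
#'   `node_id`, `node_kind`, `truncated` flag.
#' @export
build_regression <- function(node, data, candidates) {
  stopifnot(inherits(data, "gw_expression"))
  if (!node %in% data$node_ids) stop_gw("node '%s' not present in data", node)
  inc <- incoming_edges(candidates$edges, node)
  missing <- setdiff(inc$source, data$node_ids)
  if (length(missing) > 0) {
    stop_gw("candidate regulator(s) missing from data: %s",
            paste(missing, collapse = ", "))
  }
  y <- data$values[node, ]
  N <- length(y)
  kind <- data$node_kinds[[node]]

  if (nrow(inc) > 0) {
    cols <- vapply(seq_len(nrow(inc)), function(i) {
      reg <- data$values[inc$source[i], ]
      if (inc$edge_type[i] %in% c("pp", "mir_reg")) reg * y else reg
    }, numeric(N))
    cols <- matrix(cols, nrow = N)
    classes <- c(pp = "interactor", tf_reg = "TF", lnc_reg = "lncRNA",
                 mir_reg = "miRNA")[inc$edge_type]
  } else {
    cols <- matrix(numeric(0), nrow = N, ncol = 0)
    classes <- character(0)
  }
  labels <- inc$source
  edge_types <- inc$edge_type

  truncated <- FALSE
  cap <- degree_cap(N)
  if (ncol(cols) > cap) {
    r <- abs(apply(cols, 2, function(x) {
      if (stats::sd(x) == 0 || stats::sd(y) == 0) 0 else stats::cor(x, y)
    }))
    keep <- order(r, decreasing = TRUE)[seq_len(cap)]
    keep <- sort(keep)
    cols <- cols[, keep, drop = FALSE]
    labels <- labels[keep]
    classes <- classes[keep]
    edge_types <- edge_types[keep]
    truncated <- TRUE
  }

  X <- cbind(cols, 1)
  colnames(X) <- c(labels, "(basal)")
  structure(
    list(y = y, X = X, labels = labels, classes = unname(classes),
         edge_types = edge_types,
         sign_constrained = c(unname(classes) == "miRNA"),
         node_id = node, node_kind = kind, truncated = truncated),
    class = "gw_regression"
  )
}

#' Constrained least squares with nonpositive miRNA coefficients
#'
#' Minimizes `0.5 * ||X theta - y||^2` subject to `theta_j <= 0` for the
#' sign-constrained (miRNA-class) columns, leaving all other coefficients
#' free. Solved by a Lawson-Hanson-style active-set iteration: constrained
#' coefficients start clamped at zero, are released while their objective
#' gradient indicates descent into the feasible halfspace, and feasibility
#' is restored by exact line search back onto the constraint boundary.
#'
#' @param problem A `gw_regression`, or a list with elements `y`, `X` and
#'   `sign_constrained` (logical per column of `X`, recycled with FALSE for
#'   the basal column).
#' @return List with `theta` (coefficients, basal last), `residual_variance`
#'   (SSE / N), `sse`, and `rank_deficient` flag (minimum-norm convention
#'   used for unidentifiable directions).
#' @export
solve_constrained_lsq <- function(problem) {
  y <- problem$y
  X <- problem$X
  constrained <- problem$sign_constrained
  p <- ncol(X)
  if (length(constrained) < p) constrained <- c(constrained, rep(FALSE, p - length(constrained)))
  N <- length(y)
  if (N < 1) stop_gw("empty problem")

  rank_deficient <- FALSE
  # least squares on a column subset with minimum-norm fallback
  ls_fit <- function(active_cols) {
    theta <- rep(0, p)
    if (length(active_cols) == 0) return(theta)
    Xa <- X[, active_cols, drop = FALSE]
    qrx <- qr(Xa)
    if (qrx$rank < ncol(Xa)) {
      rank_deficient <<- TRUE
      sv <- svd(Xa)
      pos <- sv$d > max(sv$d[1], 1) * 1e-12
      co <- sv$v[, pos, drop = FALSE] %*%
        ((crossprod(sv$u[, pos, drop = FALSE], y)) / sv$d[pos])
      theta[active_cols] <- as.numeric(co)
    } else {
      theta[active_cols] <- qr.coef(qrx, y)
    }
    theta
  }

  clamped <- constrained            # active constraints (theta_j = 0)
  tol <- 1e-10
  theta <- ls_fit(which(!clamped))
  for (outer in seq_len(10L * p + 10L)) {
    # feasibility restoration: clamp the worst violating passive
    # constrained coordinate until the subproblem solution is feasible
    repeat {
      viol <- which(constrained & !clamped & theta > tol)
      if (length(viol) == 0) break
      clamped[viol[which.max(theta[viol])]] <- TRUE
      theta <- ls_fit(which(!clamped))
    }
    # KKT check: a clamped coefficient with positive objective gradient
    # would decrease the objective by moving into theta_j < 0 - release it
    g <- as.numeric(crossprod(X, X %*% theta - y))
    releasable <- which(clamped & g > tol * max(1, max(abs(g))))
    if (length(releasable) == 0) break
    clamped[releasable[which.max(g[releasable])]] <- FALSE
    theta <- ls_fit(which(!clamped))
  }
  theta[constrained & theta > 0] <- 0

  resid <- y - as.numeric(X %*% theta)
  sse <- sum(resid^2)
  list(theta = as.numeric(theta), residual_variance = sse / N, sse = sse,
       rank_deficient = rank_deficient)
}

#' Akaike information criterion for one node model
#'
#' Computes `log(phi^2) + 2 * (order + 1) / n_samples`, where `phi` is the
#' estimated residual error (SSE divided by the sample count) of the
#' constrained least-squares fit and `order` counts retained regulators
#' (the `+ 1` accounts for the basal level). `phi` is floored at 1e-12
#' before squaring so noiseless exact fits stay finite. The `variant`
#' argument switches to the textbook form `n * log(phi) + 2 * (order + 1)`
#' for sensitivity checks.
#'
#' @param residual_variance Estimated residual error (SSE / N), `>= 0`.
#' @param order Number of retained regulators.
#' @param n_samples Sample count N.
#' @param variant `"printed"` (default) or `"textbook"`.
#' @return AIC value (finite).
#' @export
aic_score <- function(residual_variance, order, n_samples,
                      variant = c("printed", "textbook")) {
  variant <- match.arg(variant)
  if (n_samples < 1) stop_gw("n_samples must be >= 1")
  if (residual_variance < 0) stop_gw("residual_variance must be >= 0")
  phi <- max(residual_variance, 1e-12)
  if (variant == "printed") {
    log(phi^2) + 2 * (order + 1) / n_samples
  } else {
    n_samples * log(phi) + 2 * (order + 1)
  }
}

fit_subset <- function(problem, subset) {
  p_reg <- ncol(problem$X) - 1L
  keep <- c(sort(subset), p_reg + 1L)
  sub <- list(y = problem$y,
              X = problem$X[, keep, drop = FALSE],
              sign_constrained = c(problem$sign_constrained[sort(subset)], FALSE))
  fit <- solve_constrained_lsq(sub)
  fit$subset <- sort(subset)
  fit
}

node_model_from_fit <- function(problem, fit, variant) {
  subset <- fit$subset
  k <- length(subset)
  theta_reg <- if (k > 0) fit$theta[seq_len(k)] else numeric(0)
  structure(
    list(
      node_id = problem$node_id,
      node_kind = problem$node_kind,
      selected_regulators = data.frame(
        regulator = problem$labels[subset],
        class = problem$classes[subset],
        edge_type = problem$edge_types[subset],
        estimate = theta_reg,
        stringsAsFactors = FALSE
      ),
      basal = fit$theta[k + 1L],
      residual_variance = fit$residual_variance,
      order = k,
      aic = aic_score(fit$residual_variance, k, length(problem$y), variant),
      rank_deficient = isTRUE(fit$rank_deficient)
    ),
    class = "gw_node_model"
  )
}

#' Detect the system order of one node by AIC
#'
#' Walks a greedy backward-elimination path: fit all candidate regulators,
#' then repeatedly drop the regulator with the smallest absolute estimate
#' and refit, recording the AIC at every order down to zero (basal-only).
#' Returns the model at the order minimizing AIC along the path; ties
#' (within 1e-12) go to the smaller order. Regulators eliminated by the
#' path are the node's false-positive candidates.
#'
#' @param problem A `gw_regression` from [build_regression()].
#' @param variant AIC variant, see [aic_score()].
#' @return A `gw_node_model`: selected regulators with estimates, basal
#'   level, residual variance, order, AIC, plus attribute `path` (per-order
#'   AIC trace).
#' @export
detect_order <- function(problem, variant = c("printed", "textbook")) {
  variant <- match.arg(variant)
  p_reg <- ncol(problem$X) - 1L
  subset <- seq_len(p_reg)
  fits <- vector("list", p_reg + 1L)
  fit <- fit_subset(problem, subset)
  fits[[p_reg + 1L]] <- fit
  while (length(subset) > 0) {
    k <- length(subset)
    drop_i <- which.min(abs(fit$theta[seq_len(k)]))
    subset <- subset[-drop_i]
    fit <- fit_subset(problem, subset)
    fits[[length(subset) + 1L]] <- fit
  }
  N <- length(problem$y)
  aics <- vapply(fits, function(f) {
    aic_score(f$residual_variance, length(f$subset), N, variant)
  }, numeric(1))
  best <- which(aics <= min(aics) + 1e-12)[1]  # smallest order wins ties
  model <- node_model_from_fit(problem, fits[[best]], variant)
  attr(model, "path") <- data.frame(order = seq_along(aics) - 1L, aic = aics)
  model
}

#' Exhaustive-search order detection (oracle)
#'
#' Fits every subset of candidate regulators and returns the model with the
#' exhaustive-minimum AIC (ties: smaller order, then lexicographically
#' earliest subset). Exponential in the candidate count; intended as an
#' independent oracle for validating the greedy path at small order.
#'
#' @inheritParams detect_order
#' @param max_candidates Guard against accidental exponential blow-up.
#' @return A `gw_node_model`.
#' @export
detect_order_exhaustive <- function(problem, variant = c("printed", "textbook"),
                                    max_candidates = 16L) {
  variant <- match.arg(variant)
  p_reg <- ncol(problem$X) - 1L
  if (p_reg > max_candidates) {
    stop_gw("exhaustive search refused for %d candidates (cap %d)",
            p_reg, max_candidates)
  }
  N <- length(problem$y)
  best <- NULL
  best_key <- NULL
  for (mask in 0:(2^p_reg - 1)) {
    subset <- which(bitwAnd(mask, 2^(seq_len(p_reg) - 1L)) > 0)
    fit <- fit_subset(problem, subset)
    aic <- aic_score(fit$residual_variance, length(subset), N, variant)
    key <- list(aic = aic, order = length(subset))
    better <- is.null(best) ||
      aic < best_key$aic - 1e-12 ||
      (abs(aic - best_key$aic) <= 1e-12 && length(subset) < best_key$order)
    if (better) {
      best <- fit
      best_key <- key
    }
  }
  node_model_from_fit(problem, best, variant)
}

#' Identify the real network from a candidate network and expression data
#'
#' For every node: build the regression problem over its candidate
#' regulators, solve the sign-constrained least squares, and prune false
#' positives by AIC order detection. The retained edges (with estimated
#' parameters) form the identified network; everything else in the
#' candidate network is discarded as a false positive.
#'
#' @param candidates A `gw_candidate` network.
#' @param data A `gw_expression` dataset covering all candidate nodes.
#' @param variant AIC variant, see [aic_score()].
#' @param method `"greedy"` (backward elimination, the default) or
#'   `"exhaustive"` (all-subsets oracle; exponential, desk scale only).
#' @return An object of class `gw_identified`: `edges` (source, target,
#'   edge_type, parameter — the estimated regression coefficient, so
#'   miRNA-class parameters are `<= 0`), `node_models` (per-node
#'   `gw_node_model`), `node_kinds`, and `counts` (retained nodes per class
#'   and retained regulators per class).
#' @export
identify_network <- function(candidates, data, variant = c("printed", "textbook"),
                             method = c("greedy", "exhaustive")) {
  variant <- match.arg(variant)
  method <- match.arg(method)
  stopifnot(inherits(data, "gw_expression"))
  cand_nodes <- unique(c(candidates$edges$source, candidates$edges$target))
  missing <- setdiff(cand_nodes, data$node_ids)
  if (length(missing) > 0) {
    stop_gw("candidate nodes missing from data: %s",
            paste(missing, collapse = ", "))
  }
  models <- list()
  edge_rows <- list()
  for (node in data$node_ids) {
    problem <- build_regression(node, data, candidates)
    model <- tryCatch({
      if (method == "greedy") detect_order(problem, variant)
      else detect_order_exhaustive(problem, variant, max_candidates = 20L)
    }, error = function(e) {
      stop_gw("identification failed at node '%s': %s", node, conditionMessage(e))
    })
    models[[node]] <- model
    sel <- model$selected_regulators
    if (nrow(sel) > 0) {
      edge_rows[[node]] <- data.frame(
        source = sel$regulator, target = node, edge_type = sel$edge_type,
        parameter = sel$estimate, stringsAsFactors = FALSE
      )
    }
  }
  edges <- if (length(edge_rows) > 0) do.call(rbind, edge_rows) else empty_edges()
  rownames(edges) <- NULL

  kinds <- data$node_kinds
  in_net <- unique(c(edges$source, edges$target))
  counts <- c(
    proteins = sum(kinds[in_net] %in% c("protein", "tf")),
    genes = sum(kinds[in_net] == "gene"),
    lncrnas = sum(kinds[in_net] == "lncrna"),
    mirnas = sum(kinds[in_net] == "mirna"),
    tf_regulators = length(unique(edges$source[edges$edge_type == "tf_reg"])),
    lnc_regulators = length(unique(edges$source[edges$edge_type == "lnc_reg"])),
    mir_regulators = length(unique(edges$source[edges$edge_type == "mir_reg"]))
  )
  structure(
    list(edges = edges, node_models = models, node_kinds = kinds,
         node_ids = data$node_ids, counts = counts, aic_variant = variant),
    class = "gw_identified"
  )
}

#' Edge-recovery precision, recall and F1 against a truth network
#'
#' Compares a retained edge set with the planted truth over all typed
#' edges. Protein-protein pairs are collapsed to unordered before
#' comparison, since the per-node estimation scheme identifies each
#' interaction from the target side and does not enforce symmetry.
#'
#' @param identified_edges,truth_edges Edge data.frames (source, target,
#'   edge_type).
#' @return Named numeric vector: precision, recall, f1.
#' @export
edge_f1 <- function(identified_edges, truth_edges) {
  canon <- function(df) {
    if (nrow(df) == 0) return(character(0))
    pp <- df$edge_type == "pp"
    a <- ifelse(pp, pmin(df$source, df$target), df$source)
    b <- ifelse(pp, pmax(df$source, df$target), df$target)
    unique(paste(a, b, df$edge_type))
  }
  est <- canon(identified_edges)
  tru <- canon(truth_edges)
  tp <- length(intersect(est, tru))
  precision <- if (length(est) > 0) tp / length(est) else 0
  recall <- if (length(tru) > 0) tp / length(tru) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  c(precision = precision, recall = recall, f1 = f1)
}
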