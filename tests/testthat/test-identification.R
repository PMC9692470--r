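test_that("regression problems mirror the node model structure", {
  cfg <- tiny_config(seed = 1, noise_sd = 0.01)
  nets <- generate_candidate_network(cfg)
  ds <- simulate_expression(nets$truth, cfg)

  # protein target: one bilinear column per candidate interactor + basal
  cand <- structure(list(
    edges = data.frame(source = c("P01", "P01"), target = c("P04", "P05"),
                       edge_type = "pp", stringsAsFactors = FALSE),
    node_kinds = nets$candidate$node_kinds), class = "gw_candidate")
  pb <- build_regression("P01", ds, cand)
  expect_equal(dim(pb$X), c(cfg$n_samples, 3L))
  expect_equal(pb$X[, 1], ds$values["P01", ] * ds$values["P04", ],
               ignore_attr = TRUE)
  expect_equal(pb$X[, 3], rep(1, cfg$n_samples), ignore_attr = TRUE)
  expect_false(any(pb$sign_constrained))

  # gene target: TF column raw, miRNA column product with the target,
  # constraint on the miRNA column only
  cand2 <- structure(list(
    edges = data.frame(source = c("P02", "M1"), target = "G01",
                       edge_type = c("tf_reg", "mir_reg"),
                       stringsAsFactors = FALSE),
    node_kinds = nets$candidate$node_kinds), class = "gw_candidate")
  gb <- build_regression("G01", ds, cand2)
  expect_equal(gb$X[, 1], ds$values["P02", ], ignore_attr = TRUE)
  expect_equal(gb$X[, 2], ds$values["M1", ] * ds$values["G01", ],
               ignore_attr = TRUE)
  expect_equal(gb$sign_constrained, c(FALSE, TRUE))

  # zero candidate regulators: basal-only problem, not an error
  cand3 <- structure(list(edges = gwgenr:::empty_edges(param = FALSE),
                          node_kinds = nets$candidate$node_kinds),
                     class = "gw_candidate")
  bb <- build_regression("G01", ds, cand3)
  expect_equal(ncol(bb$X), 1L)

  # a regulator missing from the data is a hard, named error
  cand4 <- structure(list(
    edges = data.frame(source = "GHOST", target = "G01",
                       edge_type = "tf_reg", stringsAsFactors = FALSE),
    node_kinds = nets$candidate$node_kinds), class = "gw_candidate")
  expect_error(build_regression("G01", ds, cand4), "GHOST")
})

test_that("over-connected nodes are truncated to fewer than half the samples", {
  set.seed(99)
  n <- 100L
  values <- matrix(stats::runif(61 * n, 0.5, 2), nrow = 61)
  ids <- c("G1", sprintf("T%02d", 1:60))
  rownames(values) <- ids
  ds <- structure(list(values = values, node_ids = ids,
                       node_kinds = stats::setNames(c("gene", rep("tf", 60)), ids),
                       sample_ids = as.character(seq_len(n))),
                  class = "gw_expression")
  cand <- structure(list(
    edges = data.frame(source = sprintf("T%02d", 1:60), target = "G1",
                       edge_type = "tf_reg", stringsAsFactors = FALSE),
    node_kinds = ds$node_kinds), class = "gw_candidate")
  pb <- build_regression("G1", ds, cand)
  expect_equal(ncol(pb$X) - 1L, floor(n / 2) - 1L)   # 49 regressors
  expect_true(pb$truncated)
})

test_that("constrained least squares matches exact algebra and the QP oracle", {
  # exact fit without basal handling: y = x exactly
  x <- c(1, 2, 3)
  fit <- solve_constrained_lsq(list(y = x, X = matrix(x, ncol = 1),
                                    sign_constrained = FALSE))
  expect_equal(fit$theta, 1)
  expect_equal(fit$residual_variance, 0)

  # an active constraint clips a positive miRNA estimate to zero
  set.seed(4)
  xr <- stats::runif(30, 0.5, 2)
  y <- 0.8 * xr + stats::rnorm(30, sd = 0.05)
  un <- solve_constrained_lsq(list(y = y, X = cbind(xr, 1),
                                   sign_constrained = c(FALSE, FALSE)))
  expect_gt(un$theta[1], 0.5)
  con <- solve_constrained_lsq(list(y = y, X = cbind(xr, 1),
                                    sign_constrained = c(TRUE, FALSE)))
  expect_lte(con$theta[1], 0)
  expect_gte(con$residual_variance, un$residual_variance)

  # seeded random problems: objective equals a projected-gradient oracle
  for (s in 1:10) {
    set.seed(s)
    X <- cbind(matrix(stats::rnorm(20 * 3), 20), 1)
    constrained <- c(TRUE, FALSE, TRUE, FALSE)
    y <- stats::rnorm(20)
    fit <- solve_constrained_lsq(list(y = y, X = X,
                                      sign_constrained = constrained))
    oracle <- pg_lsq_oracle(X, y, constrained)
    expect_equal(lsq_objective(X, y, fit$theta),
                 lsq_objective(X, y, oracle), tolerance = 1e-6)
    expect_true(all(fit$theta[constrained] <= 1e-12))
  }
})

test_that("the AIC matches its closed form and guards zero residuals", {
  expect_equal(aic_score(1, 1, 10), 0.4)
  expect_equal(aic_score(exp(1), 0, 2), 3)
  expect_true(is.finite(aic_score(0, 2, 50)))
  expect_equal(aic_score(0, 0, 10), log(1e-24) + 0.2)
  # textbook variant for sensitivity checks
  expect_equal(aic_score(exp(1), 1, 10, variant = "textbook"), 10 + 4)
})

test_that("order detection prunes noise and keeps strong regulators", {
  set.seed(10)
  n <- 100L
  # pure-noise target with 5 decoy candidates: the greedy path reaches the
  # exhaustive optimum under the default criterion; the stronger-penalty
  # textbook variant prunes all the way to the basal-only model
  X <- cbind(matrix(stats::runif(n * 5, 0.5, 2), n), 1)
  y <- stats::rnorm(n, mean = 1)
  pb <- make_problem(X, y, constrained = rep(FALSE, 5))
  expect_equal(detect_order(pb)$aic, detect_order_exhaustive(pb)$aic)
  expect_equal(detect_order(pb, variant = "textbook")$order, 0L)
  expect_equal(detect_order_exhaustive(pb, variant = "textbook")$order, 0L)

  # one strong true regulator among 3 decoys: always retained; the
  # textbook variant retains it alone
  Xs <- cbind(matrix(stats::runif(n * 4, 0.5, 2), n), 1)
  ys <- 2 * Xs[, 2] + 1 + stats::rnorm(n, sd = 0.05)
  pbs <- make_problem(Xs, ys, constrained = rep(FALSE, 4))
  mg <- detect_order(pbs)
  expect_true("r2" %in% mg$selected_regulators$regulator)
  expect_equal(abs(mg$selected_regulators$estimate[
    mg$selected_regulators$regulator == "r2"] - 2) < 0.1, TRUE)
  mt <- detect_order(pbs, variant = "textbook")
  expect_equal(mt$selected_regulators$regulator, "r2")
  me <- detect_order_exhaustive(pbs, variant = "textbook")
  expect_equal(me$selected_regulators$regulator, "r2")
  expect_equal(mt$aic, me$aic)

  # zero candidates: order-0 model with the basal-only AIC
  pb0 <- make_problem(matrix(1, n, 1), y, constrained = logical(0))
  m0 <- detect_order(pb0)
  expect_equal(m0$order, 0L)
  expect_equal(m0$aic, aic_score(m0$residual_variance, 0, n))
})

test_that("greedy backward elimination nearly always attains the exhaustive AIC", {
  hits <- 0L
  total <- 60L
  gaps <- numeric(0)
  for (i in seq_len(total)) {
    set.seed(i)
    n <- 30L
    p <- sample(2:8, 1)
    X <- cbind(matrix(stats::rnorm(n * p), n), 1)
    constrained <- stats::rbinom(p, 1, 0.3) == 1
    beta <- rep(0, p)
    k <- sample(0:p, 1)
    if (k > 0) beta[sample(p, k)] <- stats::rnorm(k)
    beta[constrained] <- -abs(beta[constrained])
    y <- as.numeric(X %*% c(beta, 1)) + stats::rnorm(n, sd = 0.5)
    pb <- make_problem(X, y, constrained)
    mg <- detect_order(pb)
    me <- detect_order_exhaustive(pb)
    expect_true(all(mg$selected_regulators$estimate[
      mg$selected_regulators$class == "miRNA"] <= 1e-12))
    if (mg$aic <= me$aic + 1e-9) hits <- hits + 1L else gaps <- c(gaps, mg$aic - me$aic)
  }
  if (length(gaps) > 0) message("greedy AIC gaps: ", paste(signif(gaps, 3), collapse = ", "))
  expect_gte(hits / total, 0.95)
})

test_that("network identification prunes decoys and recovers exact data", {
  # perfect data, candidate = truth: every edge kept, parameters exact
  cfg <- tiny_config(seed = 5, noise_sd = 0, decoy_edge_multiplier = 0)
  nets <- generate_candidate_network(cfg)
  ds <- simulate_expression(nets$truth, cfg)
  truth <- attr(ds, "truth")
  idn <- identify_network(nets$candidate, ds)
  expect_equal(unname(edge_f1(idn$edges, truth$edges)["f1"]), 1)
  m <- merge(idn$edges, truth$edges, by = c("source", "target", "edge_type"),
             suffixes = c(".est", ".tru"))
  expect_equal(nrow(m), nrow(truth$edges))
  coef_tru <- ifelse(m$edge_type == "mir_reg", -m$parameter.tru, m$parameter.tru)
  expect_lt(max(abs(m$parameter.est - coef_tru)), 1e-6)

  # pruning monotonicity and the degree cap under noise and decoys
  cfg2 <- tiny_config(seed = 6)
  nets2 <- generate_candidate_network(cfg2)
  ds2 <- simulate_expression(nets2$truth, cfg2)
  idn2 <- identify_network(nets2$candidate, ds2)
  expect_lte(nrow(idn2$edges), nrow(nets2$candidate$edges))
  orders <- vapply(idn2$node_models, function(m) m$order, integer(1))
  expect_true(all(orders <= floor(cfg2$n_samples / 2) - 1L))
  mir <- idn2$edges$parameter[idn2$edges$edge_type == "mir_reg"]
  expect_true(all(mir <= 1e-12))

  # empty candidate network -> empty identified network
  cand0 <- structure(list(edges = gwgenr:::empty_edges(param = FALSE),
                          node_kinds = ds$node_kinds), class = "gw_candidate")
  idn0 <- identify_network(cand0, ds)
  expect_equal(nrow(idn0$edges), 0L)
})
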