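test_that("class balancing down-samples the majority class exactly", {
  d <- generate_dti_dataset(dti_config(n_positive = 10L, n_negative = 100L,
                                       n_drug_features = 3L,
                                       n_target_features = 3L, seed = 2))
  b <- balance_classes(d, seed = 7)
  expect_equal(as.integer(table(b$label)), c(10L, 10L))
  expect_identical(balance_classes(d, seed = 7), b)

  even <- d[c(which(d$label == 1), which(d$label == 0)[1:10]), ]
  expect_identical(sort(rownames(balance_classes(even, seed = 1))),
                   sort(rownames(even)))
  expect_error(balance_classes(d[d$label == 0, , drop = FALSE]), "both classes")
})

test_that("standardization fits on training data and applies frozen stats", {
  x <- cbind(a = c(1, 2, 3), b = c(5, 5, 5))
  s <- standardize(x)
  expect_equal(unname(colMeans(s$values)), c(0, 0))
  expect_equal(unname(stats::sd(s$values[, 1])), 1)
  expect_true(s$stats$mask[["b"]])
  expect_true(all(s$values[, "b"] == 0))

  # hand computation on a held-out toy: (x - mu_train) / sd_train
  test_col <- cbind(a = c(0, 4, 2, 10), b = c(1, 2, 3, 4))
  applied <- standardize(test_col, s$stats)
  expect_equal(applied$values[, "a"],
               (c(0, 4, 2, 10) - 2) / 1, ignore_attr = TRUE)
  expect_true(all(applied$values[, "b"] == 0))
})

test_that("dimension reduction matches the covariance spectrum", {
  set.seed(14)
  x <- matrix(stats::rnorm(500), 50, 10)
  full <- reduce_dimensions(x, mode = "fixed_k", k = 10)
  recon <- full$values %*% t(full$basis$rotation)
  recon <- sweep(recon, 2, full$basis$center, "+")
  expect_lt(max(abs(recon - x)), 1e-10)

  rank1 <- outer(stats::rnorm(30), stats::rnorm(5))
  r <- reduce_dimensions(rank1, mode = "variance_fraction", fraction = 0.9)
  expect_equal(r$basis$k, 1L)

  # fraction rule agrees with a brute-force cumulative eigen-spectrum
  ev <- eigen(stats::cov(x), symmetric = TRUE)$values
  k_brute <- which(cumsum(ev) / sum(ev) >= 0.8)[1]
  r8 <- reduce_dimensions(x, fraction = 0.8)
  expect_equal(r8$basis$k, k_brute)

  expect_error(reduce_dimensions(x, mode = "fixed_k", k = 11), "exceeds")
})

test_that("analytic gradients agree with central finite differences", {
  set.seed(31)
  x <- matrix(stats::rnorm(18), 6, 3)
  y <- c(0, 1, 1, 0, 1, 0)
  layers <- gwgenr:::mlp_init(3, c(4L, 3L))
  fwd <- gwgenr:::mlp_forward(layers, x)
  gr <- gwgenr:::mlp_gradients(layers, fwd, y)
  loss_at <- function(l) gwgenr:::bce_loss(y, gwgenr:::mlp_predict_prob(l, x))
  eps <- 1e-6
  for (l in seq_along(layers)) {
    for (i in seq_along(layers[[l]]$W)) {
      up <- layers; up[[l]]$W[i] <- up[[l]]$W[i] + eps
      dn <- layers; dn[[l]]$W[i] <- dn[[l]]$W[i] - eps
      fd <- (loss_at(up) - loss_at(dn)) / (2 * eps)
      expect_equal(gr[[l]]$W[i], fd, tolerance = 1e-5)
    }
    for (i in seq_along(layers[[l]]$b)) {
      up <- layers; up[[l]]$b[i] <- up[[l]]$b[i] + eps
      dn <- layers; dn[[l]]$b[i] <- dn[[l]]$b[i] - eps
      fd <- (loss_at(up) - loss_at(dn)) / (2 * eps)
      expect_equal(gr[[l]]$b[i], fd, tolerance = 1e-5)
    }
  }
})

test_that("one gradient step reproduces the hand-computed update", {
  # single linear layer + sigmoid on one sample: closed-form gradient
  x <- matrix(c(1, 2), 1, 2)
  y <- 1
  layers <- list(list(W = matrix(c(0.3, -0.2), 2, 1), b = 0.1))
  fwd <- gwgenr:::mlp_forward(layers, x)
  p <- 1 / (1 + exp(-(0.3 * 1 - 0.2 * 2 + 0.1)))
  gr <- gwgenr:::mlp_gradients(layers, fwd, y)
  expect_equal(as.numeric(gr[[1]]$W), (p - 1) * c(1, 2))
  expect_equal(gr[[1]]$b, p - 1, ignore_attr = TRUE)
  eta <- 0.5
  expect_equal(as.numeric(layers[[1]]$W - eta * gr[[1]]$W),
               c(0.3, -0.2) - eta * (p - 1) * c(1, 2))
})

test_that("the ROC area equals pairwise concordance and the pROC cross-check", {
  expect_equal(evaluate_roc(c(0, 1, 0, 1), c(0, 1, 0, 1))$auc, 1)
  expect_equal(evaluate_roc(c(0, 1, 0, 1), rep(0.4, 4))$auc, 0.5)
  expect_error(evaluate_roc(c(1, 1), c(0.2, 0.8)), "both classes")

  set.seed(17)
  for (i in 1:50) {
    n <- sample(4:12, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- round(stats::runif(n), 2)   # rounding forces ties
    ev <- evaluate_roc(labels, scores)
    expect_equal(ev$auc, concordance_auc(labels, scores), tolerance = 1e-12)
  }
  skip_if_not_installed("pROC")
  set.seed(18)
  labels <- sample(0:1, 40, replace = TRUE)
  labels[1:2] <- 0:1
  scores <- stats::runif(40)
  ev <- evaluate_roc(labels, scores)
  expect_equal(ev$auc,
               as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE))),
               tolerance = 1e-10)
})

test_that("confusion counts at the 0.5 threshold satisfy the rate identities", {
  labels <- c(1, 1, 1, 0, 0, 0, 0)
  scores <- c(0.9, 0.6, 0.2, 0.8, 0.3, 0.1, 0.4)
  ev <- evaluate_roc(labels, scores)
  expect_equal(unname(ev$confusion), c(2L, 3L, 1L, 1L))  # TP TN FP FN
  expect_equal(ev$tpr, 2 / 3)
  expect_equal(ev$specificity, 3 / 4)
  expect_equal(ev$fpr, 1 - ev$specificity)
})

test_that("cross-validation folds partition the data and ace separable data", {
  d <- generate_dti_dataset(dti_config(n_drug_features = 5L,
                                       n_target_features = 5L,
                                       n_positive = 100L, n_negative = 100L,
                                       class_separation = 12, seed = 4))
  cfg <- fast_train_config(seed = 4, epochs = 200L, validation_fraction = 0)
  cv <- cross_validate(d, cfg)
  expect_equal(as.integer(sort(table(cv$fold_assignment))), rep(40L, 5))
  expect_equal(cv$fold_accuracy, rep(1, 5))
  expect_equal(cv$sd_accuracy, 0)
  cv2 <- cross_validate(d, cfg)
  expect_identical(cv, cv2)
})

test_that("training separates what is separable and nothing else", {
  d <- generate_dti_dataset(dti_config(n_drug_features = 10L,
                                       n_target_features = 10L,
                                       n_positive = 200L, n_negative = 200L,
                                       class_separation = 6, seed = 6))
  res <- run_dti(d, fast_train_config(seed = 6))
  expect_gt(res$model$history$train_accuracy[nrow(res$model$history)], 0.95)
  expect_gt(res$eval$auc, 0.95)

  shuffled <- d
  shuffled$label <- with(list(), {set.seed(60); sample(d$label)})
  res0 <- run_dti(shuffled, fast_train_config(seed = 6))
  expect_lt(abs(res0$test_accuracy - 0.5), 0.07)
})

test_that("held-out difficulty decreases with class separation", {
  aucs <- vapply(c(0, 2, 4, 6), function(sep) {
    mean(vapply(1:5, function(s) {
      d <- generate_dti_dataset(dti_config(
        n_drug_features = 10L, n_target_features = 10L,
        n_positive = 150L, n_negative = 150L,
        class_separation = sep, seed = s))
      run_dti(d, fast_train_config(seed = s, epochs = 120L))$eval$auc
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(aucs) >= 0))
})

test_that("preprocessing state is fitted on the training partition only", {
  d <- generate_dti_dataset(dti_config(n_drug_features = 6L,
                                       n_target_features = 6L,
                                       n_positive = 120L, n_negative = 150L,
                                       class_separation = 4, seed = 9))
  res <- run_dti(d, fast_train_config(seed = 9, epochs = 30L))
  train_x <- as.matrix(d[res$train_rows, setdiff(names(d), "label")])
  full <- balance_classes(d, seed = 9)
  full_x <- as.matrix(full[, setdiff(names(full), "label")])
  expect_equal(unname(res$model$scaler$means), unname(colMeans(train_x)))
  # refitting on train+test would have produced different statistics
  expect_false(isTRUE(all.equal(unname(colMeans(full_x)),
                                unname(colMeans(train_x)))))
})

test_that("candidate ranking follows the raw model probabilities", {
  d <- generate_dti_dataset(dti_config(n_drug_features = 4L,
                                       n_target_features = 4L,
                                       n_positive = 100L, n_negative = 100L,
                                       class_separation = 8, seed = 10))
  res <- run_dti(d, fast_train_config(seed = 10, epochs = 60L))
  target <- stats::setNames(rep(8 / sqrt(8), 4), sprintf("t%d", 1:4))
  set.seed(11)
  lib <- as.data.frame(matrix(stats::rnorm(40), 10, 4))
  names(lib) <- sprintf("d%d", 1:4)
  lib$drug <- sprintf("drug%02d", 1:10)
  ranked <- predict_candidates(res$model, target, lib)
  expect_equal(nrow(ranked), 10L)
  expect_true(all(ranked$probability >= 0 & ranked$probability <= 1))
  expect_equal(ranked$probability, sort(ranked$probability, decreasing = TRUE))
  # a pair resembling a training positive scores above 0.5
  pos_like <- lib[1, ]
  pos_like[1, sprintf("d%d", 1:4)] <- 8 / sqrt(8)
  p <- predict_candidates(res$model, target, pos_like)
  expect_gt(p$probability, 0.5)

  expect_equal(nrow(predict_candidates(res$model, target, lib[0, ])), 0L)
  bad <- lib
  names(bad)[1] <- "weird"
  expect_error(predict_candidates(res$model, target, bad), "weird")
})
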