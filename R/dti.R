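#' Training configuration for the drug-target interaction classifier
#'
#' Defaults follow the reference training protocol: learning rate 0.001,
#' 100 epochs, batch size 100, 5-fold cross-validation, early stopping on
#' validation loss with patience 10 (best weights restored), dropout 0.2
#' on every hidden layer, hidden layers of 512/256/128/64 rectifier units
#' and a single logistic output. Widths and epochs are parameters so the
#' same architecture runs at desk scale.
#'
#' @param learning_rate Gradient-descent step size, `> 0`.
#' @param epochs Training epochs.
#' @param batch_size Mini-batch size.
#' @param folds Cross-validation folds, `>= 2`.
#' @param patience Early-stopping patience in epochs.
#' @param dropout_rate Per-hidden-layer dropout probability in `[0, 1)`.
#' @param hidden_sizes Integer vector of hidden-layer widths.
#' @param validation_fraction Fraction of the training data held out for
#'   early stopping.
#' @param seed Integer seed for weight initialization, batching, dropout.
#' @return An object of class `gw_train_config`.
#' @export
training_config <- function(learning_rate = 0.001, epochs = 100L,
                            batch_size = 100L, folds = 5L, patience = 10L,
                            dropout_rate = 0.2,
                            hidden_sizes = c(512L, 256L, 128L, 64L),
                            validation_fraction = 0.2, seed = 1L) {
  if (learning_rate <= 0) stop_gw("learning_rate must be > 0")
  if (dropout_rate < 0 || dropout_rate >= 1) stop_gw("dropout_rate must be in [0, 1)")
  cfg <- list(
    learning_rate = learning_rate,
    epochs = check_count(epochs, "epochs"),
    batch_size = check_count(batch_size, "batch_size"),
    folds = check_count(folds, "folds", min = 2L),
    patience = check_count(patience, "patience", min = 0L),
    dropout_rate = dropout_rate,
    hidden_sizes = vapply(hidden_sizes, check_count, integer(1), name = "hidden_sizes"),
    validation_fraction = check_fraction(validation_fraction, "validation_fraction"),
    seed = check_count(seed, "seed", min = 0L)
  )
  structure(cfg, class = "gw_train_config")
}

split_features <- function(data) {
  if (!"label" %in% names(data)) stop_gw("dataset must have a 'label' column")
  list(x = as.matrix(data[, setdiff(names(data), "label"), drop = FALSE]),
       y = data$label)
}

#' Balance classes by random down-sampling
#'
#' Randomly down-samples the larger class to the size of the smaller class
#' so both labels are equally represented.
#'
#' @param data Labeled data.frame (binary `label` column).
#' @param seed Integer seed.
#' @return The balanced data.frame (original row order preserved).
#' @export
balance_classes <- function(data, seed = 1L) {
  if (!all(c(0, 1) %in% data$label)) stop_gw("both classes must be present")
  idx0 <- which(data$label == 0)
  idx1 <- which(data$label == 1)
  n <- min(length(idx0), length(idx1))
  with_seed(seed, {
    keep <- sort(c(sample_safe(idx0, n), sample_safe(idx1, n)))
    data[keep, , drop = FALSE]
  })
}

#' Standardize features (fit or apply)
#'
#' Centers and scales each feature to mean zero and unit standard
#' deviation. When `stats` is supplied (fitted on training data), the
#' stored means and deviations are applied unchanged — held-out data must
#' never refit the scaler. Zero-variance features are masked and mapped
#' to zero.
#'
#' @param x Numeric matrix (samples x features).
#' @param stats Optional fitted statistics from a previous call.
#' @return List with `values` (standardized matrix) and `stats` (means,
#'   sds, zero-variance mask).
#' @export
standardize <- function(x, stats = NULL) {
  x <- as.matrix(x)
  if (is.null(stats)) {
    if (nrow(x) < 2) stop_gw("need >= 2 samples to fit the scaler")
    means <- colMeans(x)
    sds <- apply(x, 2, stats::sd)
    stats <- list(means = means, sds = sds, mask = sds == 0)
  }
  out <- sweep(x, 2, stats$means, "-")
  sds <- ifelse(stats$mask, 1, stats$sds)
  out <- sweep(out, 2, sds, "/")
  out[, stats$mask] <- 0
  list(values = out, stats = stats)
}

#' Reduce dimensionality by principal component analysis
#'
#' Fits an orthonormal basis of leading principal directions on the
#' training data (via [stats::prcomp()]) and projects onto it. `fixed_k`
#' keeps exactly `k` components; `variance_fraction` keeps the smallest
#' number of components whose cumulative variance share reaches
#' `fraction`. A fitted `basis` is applied unchanged to held-out data.
#'
#' @param x Numeric matrix (samples x features).
#' @param mode `"variance_fraction"` (default) or `"fixed_k"`.
#' @param k Number of components for `fixed_k`.
#' @param fraction Variance fraction for `variance_fraction`.
#' @param basis Optional fitted basis from a previous call.
#' @return List with `values` (projected matrix) and `basis`.
#' @export
reduce_dimensions <- function(x, mode = c("variance_fraction", "fixed_k"),
                              k = NULL, fraction = 0.9, basis = NULL) {
  x <- as.matrix(x)
  if (is.null(basis)) {
    mode <- match.arg(mode)
    pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
    if (mode == "fixed_k") {
      if (is.null(k)) stop_gw("fixed_k mode requires `k`")
      k <- check_count(k, "k")
      if (k > ncol(x)) stop_gw("k = %d exceeds feature count %d", k, ncol(x))
    } else {
      share <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
      k <- which(share >= fraction - 1e-15)[1]
    }
    basis <- list(center = pc$center, rotation = pc$rotation[, seq_len(k), drop = FALSE],
                  k = k, mode = mode)
  }
  values <- sweep(x, 2, basis$center, "-") %*% basis$rotation
  list(values = values, basis = basis)
}

# ---- multilayer perceptron internals -------------------------------------

relu <- function(z) pmax(z, 0)
sigmoid <- function(z) 1 / (1 + exp(-z))

mlp_init <- function(input_dim, hidden_sizes) {
  sizes <- c(input_dim, hidden_sizes, 1L)
  layers <- vector("list", length(sizes) - 1L)
  for (l in seq_along(layers)) {
    fan_in <- sizes[l]
    layers[[l]] <- list(
      W = matrix(stats::rnorm(sizes[l + 1] * fan_in, sd = sqrt(2 / fan_in)),
                 nrow = fan_in),
      b = rep(0, sizes[l + 1])
    )
  }
  layers
}

# forward pass; returns activations and pre-activations for backprop.
# dropout masks (inverted dropout) are applied to hidden activations only
# when training.
mlp_forward <- function(layers, x, dropout_rate = 0, training = FALSE) {
  L <- length(layers)
  a <- list(x)
  z <- vector("list", L)
  masks <- vector("list", L)
  for (l in seq_len(L)) {
    z[[l]] <- sweep(a[[l]] %*% layers[[l]]$W, 2, layers[[l]]$b, "+")
    if (l < L) {
      h <- relu(z[[l]])
      if (training && dropout_rate > 0) {
        m <- matrix(stats::rbinom(length(h), 1, 1 - dropout_rate),
                    nrow = nrow(h)) / (1 - dropout_rate)
        h <- h * m
        masks[[l]] <- m
      }
      a[[l + 1]] <- h
    } else {
      a[[l + 1]] <- sigmoid(z[[l]])
    }
  }
  list(a = a, z = z, masks = masks)
}

bce_loss <- function(y, yhat) {
  yhat <- pmin(pmax(yhat, 1e-12), 1 - 1e-12)
  -mean(y * log(yhat) + (1 - y) * log(1 - yhat))
}

# gradients of the mean binary cross-entropy w.r.t. all weights/biases
mlp_gradients <- function(layers, fwd, y) {
  L <- length(layers)
  n <- length(y)
  grads <- vector("list", L)
  delta <- (fwd$a[[L + 1]] - y) / n      # sigmoid + BCE shortcut
  for (l in rev(seq_len(L))) {
    grads[[l]] <- list(W = crossprod(fwd$a[[l]], delta),
                       b = colSums(delta))
    if (l > 1) {
      delta <- (delta %*% t(layers[[l]]$W)) * (fwd$z[[l - 1]] > 0)
      if (!is.null(fwd$masks[[l - 1]])) delta <- delta * fwd$masks[[l - 1]]
    }
  }
  grads
}

mlp_predict_prob <- function(layers, x) {
  as.numeric(mlp_forward(layers, x)$a[[length(layers) + 1]])
}

#' Train the feedforward drug-target interaction classifier
#'
#' Minimizes the mean binary cross-entropy by plain mini-batch gradient
#' descent (`theta <- theta - eta * grad`), with rectifier hidden layers, a
#' logistic output unit, inverted dropout active only during training, and
#' early stopping on validation loss (best weights restored). The input is
#' expected to be balanced, standardized and dimension-reduced already; use
#' [run_dti()] for the full leakage-safe pipeline.
#'
#' @param data Labeled data.frame (feature columns plus `label`).
#' @param config A [training_config()].
#' @return An object of class `gw_mlp`: `layers` (weights/biases),
#'   `config`, `history` (per-epoch training/validation loss and accuracy),
#'   `feature_names`, and optionally bound `scaler`/`basis` state.
#' @export
train_dnn <- function(data, config = training_config()) {
  stopifnot(inherits(config, "gw_train_config"))
  d <- split_features(data)
  n <- nrow(d$x)
  with_seed(config$seed, {
    n_val <- floor(config$validation_fraction * n)
    val_idx <- if (n_val > 0) sample.int(n, n_val) else integer(0)
    tr_idx <- setdiff(seq_len(n), val_idx)
    xt <- d$x[tr_idx, , drop = FALSE]; yt <- d$y[tr_idx]
    xv <- d$x[val_idx, , drop = FALSE]; yv <- d$y[val_idx]

    layers <- mlp_init(ncol(d$x), config$hidden_sizes)
    history <- data.frame()
    best_layers <- layers
    best_loss <- Inf
    wait <- 0L
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(nrow(xt))
      for (start in seq(1, nrow(xt), by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, nrow(xt))]
        fwd <- mlp_forward(layers, xt[idx, , drop = FALSE],
                           config$dropout_rate, training = TRUE)
        grads <- mlp_gradients(layers, fwd, yt[idx])
        for (l in seq_along(layers)) {
          layers[[l]]$W <- layers[[l]]$W - config$learning_rate * grads[[l]]$W
          layers[[l]]$b <- layers[[l]]$b - config$learning_rate * grads[[l]]$b
        }
      }
      pt <- mlp_predict_prob(layers, xt)
      train_loss <- bce_loss(yt, pt)
      if (!is.finite(train_loss)) stop_gw("non-finite training loss at epoch %d", epoch)
      monitor <- if (length(val_idx) > 0) {
        pv <- mlp_predict_prob(layers, xv)
        c(loss = bce_loss(yv, pv), acc = mean((pv > 0.5) == yv))
      } else c(loss = train_loss, acc = NA_real_)
      history <- rbind(history, data.frame(
        epoch = epoch, train_loss = train_loss,
        train_accuracy = mean((pt > 0.5) == yt),
        val_loss = monitor[["loss"]], val_accuracy = monitor[["acc"]]
      ))
      if (monitor[["loss"]] < best_loss - 1e-9) {
        best_loss <- monitor[["loss"]]
        best_layers <- layers
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience && config$patience > 0) break
      }
    }
    structure(
      list(layers = best_layers, config = config, history = history,
           feature_names = colnames(d$x), scaler = NULL, basis = NULL),
      class = "gw_mlp"
    )
  })
}

#' @export
predict.gw_mlp <- function(object, newdata, preprocess = TRUE, ...) {
  x <- if (is.data.frame(newdata)) {
    as.matrix(newdata[, setdiff(names(newdata), "label"), drop = FALSE])
  } else as.matrix(newdata)
  if (preprocess) {
    if (!is.null(object$scaler)) x <- standardize(x, object$scaler)$values
    if (!is.null(object$basis)) x <- reduce_dimensions(x, basis = object$basis)$values
  }
  mlp_predict_prob(object$layers, x)
}

#' k-fold cross-validation of the classifier
#'
#' Splits the data into `config$folds` equal parts; each part serves as
#' validation exactly once while the model is trained on the rest.
#' Standardization and dimensionality reduction are refitted inside every
#' fold on the training part only, so no information leaks from the
#' held-out part.
#'
#' @param data Labeled data.frame (raw feature scale).
#' @param config A [training_config()].
#' @param reduce_fraction Variance fraction for the per-fold PCA.
#' @return List with `fold_accuracy`, `mean_accuracy`, `sd_accuracy`,
#'   `fold_assignment`.
#' @export
cross_validate <- function(data, config = training_config(),
                           reduce_fraction = 0.9) {
  n <- nrow(data)
  if (config$folds > n) stop_gw("more folds than samples")
  assignment <- with_seed(config$seed,
                          sample(rep_len(seq_len(config$folds), n)))
  acc <- numeric(config$folds)
  for (f in seq_len(config$folds)) {
    tr <- data[assignment != f, , drop = FALSE]
    va <- data[assignment == f, , drop = FALSE]
    dtr <- split_features(tr)
    std <- standardize(dtr$x)
    red <- reduce_dimensions(std$values, fraction = reduce_fraction)
    tr_proc <- as.data.frame(red$values)
    tr_proc$label <- dtr$y
    model <- train_dnn(tr_proc, config)
    model$scaler <- std$stats
    model$basis <- red$basis
    p <- predict(model, va)
    acc[f] <- mean((p > 0.5) == va$label)
  }
  list(fold_accuracy = acc, mean_accuracy = mean(acc),
       sd_accuracy = stats::sd(acc), fold_assignment = assignment)
}

#' ROC curve, AUC and confusion counts
#'
#' Sweeps the decision threshold over the unique scores to trace the ROC
#' curve, integrates it by the trapezoid rule for the AUC, and reports
#' confusion counts (TP/TN/FP/FN), sensitivity (TPR), specificity and FPR
#' at the 0.5 threshold.
#'
#' @param labels Binary labels.
#' @param scores Predicted probabilities or scores.
#' @return An object of class `gw_eval`: `roc` (data.frame threshold, fpr,
#'   tpr), `auc`, `confusion`, `tpr`, `specificity`, `fpr`.
#' @export
evaluate_roc <- function(labels, scores) {
  if (length(unique(labels)) < 2) stop_gw("both classes must be present")
  thresholds <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pos <- sum(labels == 1)
  neg <- sum(labels == 0)
  tpr <- vapply(thresholds, function(t) sum(scores >= t & labels == 1) / pos,
                numeric(1))
  fpr <- vapply(thresholds, function(t) sum(scores >= t & labels == 0) / neg,
                numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  tp <- sum(scores > 0.5 & labels == 1)
  fp <- sum(scores > 0.5 & labels == 0)
  fn <- pos - tp
  tn <- neg - fp
  structure(
    list(roc = data.frame(threshold = thresholds, fpr = fpr, tpr = tpr),
         auc = auc,
         confusion = c(TP = tp, TN = tn, FP = fp, FN = fn),
         tpr = tp / (tp + fn), specificity = tn / (tn + fp),
         fpr = 1 - tn / (tn + fp)),
    class = "gw_eval"
  )
}

#' Full leakage-safe DTI pipeline
#'
#' Balances the classes, splits three quarters for training and one
#' quarter for testing, fits the scaler and the PCA basis on the training
#' partition only, trains the network and evaluates on the untouched test
#' partition.
#'
#' @param data Labeled data.frame (raw feature scale).
#' @param config A [training_config()].
#' @param reduce_mode,reduce_k,reduce_fraction Dimension-reduction settings
#'   passed to [reduce_dimensions()].
#' @return List with `model` (a `gw_mlp` with bound scaler/basis), `eval`
#'   (a `gw_eval` on the test partition), `test_accuracy`, and the
#'   train/test row indices.
#' @export
run_dti <- function(data, config = training_config(),
                    reduce_mode = "variance_fraction", reduce_k = NULL,
                    reduce_fraction = 0.9) {
  balanced <- balance_classes(data, seed = config$seed)
  n <- nrow(balanced)
  idx <- with_seed(config$seed + 1L, sample.int(n))
  n_train <- floor(3 * n / 4)
  tr <- balanced[idx[seq_len(n_train)], , drop = FALSE]
  te <- balanced[idx[-seq_len(n_train)], , drop = FALSE]
  dtr <- split_features(tr)
  std <- standardize(dtr$x)
  red <- reduce_dimensions(std$values, mode = reduce_mode, k = reduce_k,
                           fraction = reduce_fraction)
  tr_proc <- as.data.frame(red$values)
  tr_proc$label <- dtr$y
  model <- train_dnn(tr_proc, config)
  model$scaler <- std$stats
  model$basis <- red$basis
  p <- predict(model, te)
  eval <- evaluate_roc(te$label, p)
  list(model = model, eval = eval,
       test_accuracy = mean((p > 0.5) == te$label),
       train_rows = rownames(tr), test_rows = rownames(te))
}

#' Rank a drug library against one target
#'
#' Concatenates each library drug's features with the target's feature
#' vector, pushes the pairs through the trained interaction model (with
#' its bound scaler and projection basis) and ranks drugs by predicted
#' interaction probability.
#'
#' @param model A trained `gw_mlp` with bound preprocessing state.
#' @param target_features Named numeric vector of target features.
#' @param drug_library Data.frame of drug feature rows (rownames or a
#'   `drug` column identify the drugs).
#' @param cutoff Minimum probability to report (default 0: report all).
#' @return Data.frame (drug, probability), sorted by descending
#'   probability.
#' @export
predict_candidates <- function(model, target_features, drug_library,
                               cutoff = 0) {
  drug_names <- if ("drug" %in% names(drug_library)) {
    drug_library$drug
  } else rownames(drug_library)
  feat <- drug_library[, setdiff(names(drug_library), "drug"), drop = FALSE]
  if (nrow(feat) == 0) {
    return(data.frame(drug = character(0), probability = numeric(0)))
  }
  z <- cbind(as.matrix(feat),
             matrix(rep(target_features, each = nrow(feat)), nrow = nrow(feat),
                    dimnames = list(NULL, names(target_features))))
  expected <- if (!is.null(model$scaler)) names(model$scaler$means) else model$feature_names
  if (!is.null(expected)) {
    missing <- setdiff(expected, colnames(z))
    extra <- setdiff(colnames(z), expected)
    if (length(missing) > 0 || length(extra) > 0) {
      stop_gw("feature schema mismatch; missing: [%s], unexpected: [%s]",
              paste(missing, collapse = ", "), paste(extra, collapse = ", "))
    }
    z <- z[, expected, drop = FALSE]
  }
  p <- predict(model, z)
  out <- data.frame(drug = drug_names, probability = p,
                    stringsAsFactors = FALSE)
  out <- out[out$probability >= cutoff, , drop = FALSE]
  out <- out[order(-out$probability, out$drug), , drop = FALSE]
  rownames(out) <- NULL
  out
}
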