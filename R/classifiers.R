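#' Reference classifier: single-hidden-layer ReLU multi-layer perceptron
#'
#' The reference model used throughout the audit battery: a multi-layer
#' perceptron with one hidden layer of `hidden_units` rectified-linear
#' units and a softmax output trained by full-batch Adam on the
#' cross-entropy objective. Presets of 10 and 256 hidden units cover the
#' small-feature and rich-feature regimes. There is no early stopping --
#' early stopping would itself require a validation split -- so an
#' over-parameterized configuration drives the training error toward zero,
#' which is exactly the regime the no-validation diagnostic exploits.
#'
#' Training is deterministic given (spec, data, seed), and with full-batch
#' updates it is invariant to the order of the training rows.
#'
#' @param hidden_units hidden-layer width `H >= 1`.
#' @param epochs training epochs (`>= 1`).
#' @param learning_rate Adam step size.
#' @param batch_size minibatch size, or `NULL` for full batch (default).
#' @param l2 optional weight decay.
#' @param seed integer seed for weight initialization (and minibatch order).
#' @return A classifier specification of class `c("mlp_spec",
#'   "classifier_spec")`, usable with [fit_classifier] and [run_scheme].
#' @export
mlp_classifier <- function(hidden_units = 10L, epochs = 200L,
                           learning_rate = 0.01, batch_size = NULL,
                           l2 = 0, seed = 1L) {
  assert_that(hidden_units >= 1, "hidden_units must be >= 1")
  assert_that(epochs >= 1, "epochs must be >= 1")
  structure(list(hidden_units = as.integer(hidden_units),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 batch_size = batch_size, l2 = l2,
                 seed = as.integer(seed)),
            class = c("mlp_spec", "classifier_spec"))
}

#' Fast baseline classifier: nearest class centroid
#'
#' A deterministic linear baseline honoring the same fit/score contract as
#' the reference network: per-class feature centroids, with class scores
#' from a softmax over negative squared distances. Useful where thousands
#' of refits are needed (permutation tests, Monte-Carlo calibration) and
#' the expressiveness of the network is not the point.
#'
#' @param scale softmax temperature on the negative squared distances.
#' @return A classifier specification of class `c("centroid_spec",
#'   "classifier_spec")`.
#' @export
centroid_classifier <- function(scale = 1) {
  structure(list(scale = scale),
            class = c("centroid_spec", "classifier_spec"))
}

#' Fit a classifier specification
#'
#' Generic entry point of the pluggable classifier contract: any method
#' that accepts `(spec, x, y, seed)` and returns an object with a
#' [predict_scores] method can be audited. Training labels must contain at
#' least two classes.
#'
#' @param spec a `classifier_spec`.
#' @param x numeric training matrix.
#' @param y training labels (factor).
#' @param seed optional integer overriding the spec's seed.
#' @return A fitted model object.
#' @export
fit_classifier <- function(spec, x, y, seed = NULL) {
  UseMethod("fit_classifier")
}

#' Per-class scores of a fitted classifier
#'
#' @param model a fitted model from [fit_classifier].
#' @param x numeric matrix of instances to score.
#' @return An `N x C` matrix of class probabilities (rows sum to 1),
#'   columns named by class.
#' @export
predict_scores <- function(model, x) UseMethod("predict_scores")

check_training_labels <- function(y) {
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2)
    fail("training labels contain a single class; cannot fit a classifier")
  y
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' @export
fit_classifier.mlp_spec <- function(spec, x, y, seed = NULL) {
  y <- check_training_labels(y)
  x <- as.matrix(x)
  n <- nrow(x); d <- ncol(x)
  h <- spec$hidden_units
  classes <- levels(y)
  C <- length(classes)
  Y <- diag(C)[as.integer(y), , drop = FALSE]   # one-hot targets
  seed <- seed %||% spec$seed
  params <- withr::with_seed(seed, list(
    W1 = matrix(stats::rnorm(d * h, sd = sqrt(2 / d)), d, h),
    b1 = numeric(h),
    W2 = matrix(stats::rnorm(h * C, sd = sqrt(2 / h)), h, C),
    b2 = numeric(C)))
  # Adam state
  mom <- lapply(params, function(p) p * 0)
  vel <- lapply(params, function(p) p * 0)
  b1m <- 0.9; b2m <- 0.999; eps <- 1e-8
  lr <- spec$learning_rate
  step <- 0L
  batches_for_epoch <- function(ep) {
    if (is.null(spec$batch_size) || spec$batch_size >= n)
      return(list(seq_len(n)))
    perm <- withr::with_seed(derive_seed(seed, ep), sample.int(n))
    split(perm, ceiling(seq_along(perm) / spec$batch_size))
  }
  for (ep in seq_len(spec$epochs)) {
    for (idx in batches_for_epoch(ep)) {
      xb <- x[idx, , drop = FALSE]
      yb <- Y[idx, , drop = FALSE]
      a1 <- sweep(xb %*% params$W1, 2, params$b1, `+`)
      hft <- pmax(a1, 0)
      z <- sweep(hft %*% params$W2, 2, params$b2, `+`)
      p <- softmax_rows(z)
      gz <- (p - yb) / nrow(xb)
      grads <- list(
        W1 = crossprod(xb, (gz %*% t(params$W2)) * (a1 > 0)) +
          spec$l2 * params$W1,
        b1 = colSums((gz %*% t(params$W2)) * (a1 > 0)),
        W2 = crossprod(hft, gz) + spec$l2 * params$W2,
        b2 = colSums(gz))
      step <- step + 1L
      for (nm in names(params)) {
        mom[[nm]] <- b1m * mom[[nm]] + (1 - b1m) * grads[[nm]]
        vel[[nm]] <- b2m * vel[[nm]] + (1 - b2m) * grads[[nm]]^2
        mhat <- mom[[nm]] / (1 - b1m^step)
        vhat <- vel[[nm]] / (1 - b2m^step)
        params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      }
    }
  }
  structure(list(params = params, classes = classes, spec = spec),
            class = "mlp_model")
}

#' @export
predict_scores.mlp_model <- function(model, x) {
  x <- as.matrix(x)
  p <- model$params
  hft <- pmax(sweep(x %*% p$W1, 2, p$b1, `+`), 0)
  z <- sweep(hft %*% p$W2, 2, p$b2, `+`)
  out <- softmax_rows(z)
  colnames(out) <- model$classes
  out
}

#' @export
fit_classifier.centroid_spec <- function(spec, x, y, seed = NULL) {
  y <- check_training_labels(y)
  x <- as.matrix(x)
  cent <- do.call(rbind, lapply(split(seq_along(y), y),
                                function(i) colMeans(x[i, , drop = FALSE])))
  structure(list(centroids = cent, classes = levels(y), scale = spec$scale),
            class = "centroid_model")
}

#' @export
predict_scores.centroid_model <- function(model, x) {
  x <- as.matrix(x)
  d2 <- vapply(seq_len(nrow(model$centroids)), function(j)
    rowSums(sweep(x, 2, model$centroids[j, ], `-`)^2),
    numeric(nrow(x)))
  if (nrow(x) == 1) d2 <- matrix(d2, nrow = 1)
  out <- softmax_rows(-model$scale * d2 / 2)
  colnames(out) <- model$classes
  out
}

#' Hard class predictions from score matrix
#' @param scores matrix from [predict_scores].
#' @return factor of argmax classes (ties to the first class).
#' @export
predicted_classes <- function(scores) {
  factor(colnames(scores)[max.col(scores, ties.method = "first")],
         levels = colnames(scores))
}

# metric on one eval fold; scores has one column per training class
fold_metric <- function(metric, scores, truth) {
  switch(metric,
    accuracy = accuracy(predicted_classes(scores), truth),
    balanced_accuracy = balanced_accuracy(predicted_classes(scores), truth),
    auc = {
      if (ncol(scores) != 2)
        fail("metric 'auc' requires a binary task")
      pos <- colnames(scores)[2]
      if (length(unique(truth == pos)) < 2) {
        warning("eval fold contains a single class; fold AUC undefined (NA)",
                call. = FALSE)
        NA_real_
      } else {
        auc_binary(scores[, 2], truth == pos)
      }
    },
    fail("unknown metric: ", metric))
}

#' Train and evaluate a classifier over a fold assignment
#'
#' For every fold the model is refit from scratch on the training rows
#' only; preprocessing statistics (feature mean and scale, on by default)
#' are estimated on the fold's training rows only and applied unchanged to
#' the eval rows, so no eval instance ever influences fitting. The fold
#' metric is computed on the eval rows; the aggregate is the arithmetic
#' mean and standard deviation over folds.
#'
#' If an eval fold contains a class absent from its training fold, accuracy
#' is computed normally and balanced accuracy drops the absent class with a
#' warning; a single-class eval fold leaves that fold's AUC undefined (NA,
#' with a warning) and the aggregate averages the defined folds.
#'
#' @param tab a [sample_table].
#' @param assignment a `fold_assignment` (or scheme spec for [make_folds]).
#' @param spec a `classifier_spec`.
#' @param metric `"accuracy"`, `"balanced_accuracy"`, or `"auc"`.
#' @param standardize estimate per-fold feature standardization on the
#'   training rows (default `TRUE`).
#' @param keep_models retain fitted model objects per fold.
#' @return An object of class `fold_scores`: per-fold metric values,
#'   per-instance eval scores, aggregate `mean` and `sd`, and metadata.
#' @export
run_scheme <- function(tab, assignment, spec, metric = "accuracy",
                       standardize = TRUE, keep_models = FALSE) {
  assignment <- make_folds(tab, assignment)
  k <- length(assignment$folds)
  fold_values <- numeric(k)
  fold_scores_list <- vector("list", k)
  models <- if (keep_models) vector("list", k) else NULL
  for (j in seq_len(k)) {
    f <- assignment$folds[[j]]
    xtr <- tab$features[f$train, , drop = FALSE]
    xev <- tab$features[f$eval, , drop = FALSE]
    if (standardize) {
      mu <- colMeans(xtr)
      sc <- apply(xtr, 2, stats::sd)
      sc[sc == 0] <- 1
      xtr <- sweep(sweep(xtr, 2, mu), 2, sc, `/`)
      xev <- sweep(sweep(xev, 2, mu), 2, sc, `/`)
    }
    model <- fit_classifier(spec, xtr, tab$labels[f$train],
                            seed = derive_seed(spec$seed %||% 1L, j))
    sc_ev <- predict_scores(model, xev)
    fold_values[j] <- fold_metric(metric, sc_ev, droplevels(tab$labels[f$eval]))
    fold_scores_list[[j]] <- sc_ev
    if (keep_models) models[[j]] <- model
  }
  structure(list(metric = metric,
                 fold_values = fold_values,
                 mean = mean(fold_values, na.rm = TRUE),
                 sd = if (k > 1) stats::sd(fold_values[!is.na(fold_values)])
                      else NA_real_,
                 scores = fold_scores_list,
                 models = models,
                 scheme = assignment$scheme,
                 level = assignment$level,
                 k = k,
                 notes = assignment$notes),
            class = "fold_scores")
}

#' @export
print.fold_scores <- function(x, ...) {
  cat(sprintf("<fold_scores> %s%s k=%d  %s = %.3f (%s)\n",
              x$scheme,
              if (!is.null(x$level)) paste0("(", x$level, ")") else "",
              x$k, x$metric, x$mean,
              if (is.na(x$sd)) "N/A" else sprintf("%.3f", x$sd)))
  if (!is.null(x$notes)) cat("  note:", x$notes, "\n")
  invisible(x)
}
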