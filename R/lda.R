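#' Binary LDA model container
#'
#' Internal constructor assembling a fitted (or manually specified) linear
#' discriminant model. The decision function is `D(x) = w'x + b` with
#' `w = Sigma^-1 (mu2 - mu1)` and `b = -w' (mu1 + mu2) / 2`; the sign of
#' `D(x)` assigns class 1 (negative) or class 2 (positive).
#'
#' @param mu1,mu2 Class mean vectors.
#' @param sigma Pooled (common) covariance matrix.
#' @param sigma_inv Its inverse.
#' @param n_samples Running count of feature samples incorporated.
#' @param class_counts Named numeric vector of per-class sample counts.
#' @param regularization Shrinkage coefficient used at training time.
#' @return An object of class `lda_model`.
#' @keywords internal
#' @export
new_lda_model <- function(mu1, mu2, sigma, sigma_inv, n_samples,
                          class_counts, regularization = 0) {
  w <- drop(sigma_inv %*% (mu2 - mu1))
  b <- -sum(w * (mu1 + mu2)) / 2
  structure(
    list(
      mu1 = as.numeric(mu1), mu2 = as.numeric(mu2),
      sigma = sigma, sigma_inv = sigma_inv,
      w = w, b = b,
      n_samples = n_samples,
      class_counts = class_counts,
      regularization = regularization,
      update_count = 0L
    ),
    class = "lda_model"
  )
}

refresh_hyperplane <- function(model) {
  model$w <- drop(model$sigma_inv %*% (model$mu2 - model$mu1))
  model$b <- -sum(model$w * (model$mu1 + model$mu2)) / 2
  model
}

#' Train a static binary LDA classifier
#'
#' Estimates per-class means and the pooled within-class covariance from a
#' window-by-feature matrix, optionally shrinking the covariance toward its
#' diagonal, and derives the separating hyperplane. The pooled covariance uses
#' within-class centring with denominator `N - 2` (two estimated means).
#'
#' @param features A [feature_matrix] containing windows of both classes.
#' @param regularization Shrinkage coefficient in `[0, 1]`: the covariance is
#'   replaced by `(1 - r) * S + r * diag(diag(S))`. High-dimensional spectral
#'   feature spaces routinely make `S` ill-conditioned, so a small default is
#'   applied (`1e-3`).
#' @return An `lda_model`.
#' @examples
#' fm <- feature_matrix(
#'   X = rbind(matrix(rnorm(20), 10), matrix(rnorm(20, 2), 10)),
#'   window_trial = rep(1:4, each = 5),
#'   window_label = rep(c(1, 2), each = 10)
#' )
#' train_lda(fm)
#' @export
train_lda <- function(features, regularization = 1e-3) {
  stopifnot(inherits(features, "feature_matrix"))
  check_fraction(regularization, "regularization")
  X <- features$X
  y <- features$window_label
  n1 <- sum(y == 1L); n2 <- sum(y == 2L)
  if (n1 < 2L || n2 < 2L) {
    abort_bad("both classes must be present with at least 2 samples each.")
  }
  X1 <- X[y == 1L, , drop = FALSE]
  X2 <- X[y == 2L, , drop = FALSE]
  mu1 <- colMeans(X1)
  mu2 <- colMeans(X2)
  n <- n1 + n2
  S <- (crossprod(sweep(X1, 2, mu1, check.margin = FALSE)) +
          crossprod(sweep(X2, 2, mu2, check.margin = FALSE))) / (n - 2)
  if (regularization > 0) {
    S <- (1 - regularization) * S +
      regularization * diag(diag(S), ncol(X))
  }
  singular <- function() {
    abort_bad(paste(
      "pooled covariance is singular; increase `regularization`",
      "(shrinkage toward the diagonal) or reduce the feature dimension."
    ))
  }
  R <- tryCatch(chol(S), error = function(e) singular())
  # Cholesky pivots give a cheap rank check: a (near-)dependent feature shows
  # up as a pivot at rounding-noise scale even when chol() itself succeeds
  if (min(diag(R))^2 <= ncol(X) * .Machine$double.eps * max(diag(S))) singular()
  sigma_inv <- chol2inv(R)
  new_lda_model(
    mu1 = mu1, mu2 = mu2, sigma = S, sigma_inv = sigma_inv,
    n_samples = n, class_counts = c(`1` = n1, `2` = n2),
    regularization = regularization
  )
}

#' @export
print.lda_model <- function(x, ...) {
  cat(sprintf("<lda_model> %d features, trained on %d samples (class 1: %d, class 2: %d)\n",
              length(x$w), x$n_samples, x$class_counts[["1"]], x$class_counts[["2"]]))
  cat(sprintf("  |w| = %.4g, b = %.4g, shrinkage = %g\n",
              sqrt(sum(x$w^2)), x$b, x$regularization))
  invisible(x)
}

as_feature_rows <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  if (ncol(x) != length(model$w)) {
    abort_bad(sprintf("feature dimension mismatch: model has %d, input has %d.",
                      length(model$w), ncol(x)))
  }
  x
}

#' Signed distance from the separating hyperplane
#'
#' Computes `D(x) = w'x + b` for one feature vector or a matrix of feature
#' rows. Negative distances map to class 1, positive to class 2.
#'
#' @param model An `lda_model`.
#' @param x Numeric feature vector, or matrix with one feature vector per row.
#' @return Numeric vector of signed distances.
#' @export
decision <- function(model, x) {
  stopifnot(inherits(model, "lda_model"))
  drop(as_feature_rows(model, x) %*% model$w + model$b)
}

#' Probability of class 2 from the decision value
#'
#' Strictly increasing logistic map of the signed distance with
#' `D = 0 -> 0.5`, so thresholding the probability at 0.5 reproduces the sign
#' rule exactly.
#'
#' @inheritParams decision
#' @return Numeric vector of probabilities in (0, 1).
#' @export
probability <- function(model, x) {
  stats::plogis(decision(model, x))
}

#' Predicted class labels
#'
#' @inheritParams decision
#' @param type One of `"class"`, `"distance"`, `"probability"`.
#' @param ... Unused.
#' @return Class labels (1/2), signed distances, or class-2 probabilities.
#' @export
predict.lda_model <- function(object, x,
                              type = c("class", "distance", "probability"),
                              ...) {
  type <- match.arg(type)
  d <- decision(object, x)
  switch(type,
    class = ifelse(d > 0, 2L, 1L),
    distance = d,
    probability = stats::plogis(d)
  )
}

#' Trial-stratified k-fold cross-validated accuracy
#'
#' Folds are stratified by class and split at the trial level, so all windows
#' of a trial land in the same fold and overlapping windows never leak between
#' training and test sets. Returns the mean window-level accuracy across
#' folds, as a percentage.
#'
#' @param features A [feature_matrix].
#' @param k Number of folds (default 8).
#' @param seed Optional RNG seed controlling the fold assignment.
#' @param regularization Shrinkage passed to [train_lda()].
#' @return Cross-validated accuracy in percent, in `[0, 100]`.
#' @export
cross_validated_accuracy <- function(features, k = 8, seed = NULL,
                                     regularization = 1e-3) {
  stopifnot(inherits(features, "feature_matrix"))
  if (!is_count(k) || k < 2) abort_bad("`k` must be an integer >= 2.")
  trial_label <- tapply(features$window_label, features$window_trial, `[`, 1L)
  trials <- as.integer(names(trial_label))
  t1 <- trials[trial_label == 1L]
  t2 <- trials[trial_label == 2L]
  if (k > min(length(t1), length(t2))) {
    abort_bad("`k` exceeds the number of trials available in a class.")
  }
  fold <- integer(max(trials))
  with_seed_opt(seed, {
    fold[sample(t1)] <- rep_len(seq_len(k), length(t1))
    fold[sample(t2)] <- rep_len(seq_len(k), length(t2))
  })
  window_fold <- fold[features$window_trial]

  acc <- vapply(seq_len(k), function(f) {
    train <- subset_windows(features, window_fold != f)
    test <- subset_windows(features, window_fold == f)
    model <- train_lda(train, regularization = regularization)
    pred <- predict(model, test$X, type = "class")
    mean(pred == test$window_label)
  }, numeric(1))
  100 * mean(acc)
}

#' @rdname tidy.lda_model
#' @export
glance.lda_model <- function(x, ...) {
  tibble::tibble(
    n_features = length(x$w),
    n_samples = x$n_samples,
    n_class1 = unname(x$class_counts[["1"]]),
    n_class2 = unname(x$class_counts[["2"]]),
    bias = x$b,
    w_norm = sqrt(sum(x$w^2)),
    regularization = x$regularization
  )
}

#' Tidy the hyperplane of a fitted LDA model
#'
#' @param x An `lda_model`.
#' @param ... Unused.
#' @return `tidy()`: a tibble with one row per feature (`term`, `weight`,
#'   `mu1`, `mu2`); `glance()`: a one-row model summary.
#' @export
tidy.lda_model <- function(x, ...) {
  terms <- names(x$w)
  if (is.null(terms)) terms <- paste0("f", seq_along(x$w))
  tibble::tibble(term = terms, weight = unname(x$w),
                 mu1 = x$mu1, mu2 = x$mu2)
}
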