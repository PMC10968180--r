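#' Update-coefficient pair
#'
#' The adaptive classifier is governed by two scalar update coefficients in
#' `[0, 1]`: `uc_mu` sets the speed at which a class mean tracks new feature
#' samples, `uc_sigma` the speed of the common covariance update. Values near
#' zero keep the model close to its calibration; values near one chase the
#' newest samples.
#'
#' @param uc_mu Mean update coefficient in `[0, 1]`.
#' @param uc_sigma Covariance update coefficient in `[0, 1)`; exactly 1 would
#'   annihilate the previous covariance and leave a singular rank-one matrix.
#' @return A named list of class `uc_pair`.
#' @export
uc_pair <- function(uc_mu, uc_sigma) {
  check_fraction(uc_mu, "uc_mu")
  check_fraction(uc_sigma, "uc_sigma", closed_upper = FALSE)
  structure(list(uc_mu = uc_mu, uc_sigma = uc_sigma), class = "uc_pair")
}

as_uc_pair <- function(uc) {
  if (inherits(uc, "uc_pair")) return(uc)
  if (is.numeric(uc) && length(uc) == 2L) {
    nm <- names(uc)
    if (!is.null(nm) && all(c("uc_mu", "uc_sigma") %in% nm)) {
      return(uc_pair(uc[["uc_mu"]], uc[["uc_sigma"]]))
    }
    return(uc_pair(uc[[1]], uc[[2]]))
  }
  if (is.list(uc) && all(c("uc_mu", "uc_sigma") %in% names(uc))) {
    return(uc_pair(uc$uc_mu, uc$uc_sigma))
  }
  abort_bad("`uc` must be a uc_pair or a length-2 numeric (uc_mu, uc_sigma).")
}

#' @export
print.uc_pair <- function(x, ...) {
  cat(sprintf("<uc_pair> uc_mu = %g, uc_sigma = %g\n", x$uc_mu, x$uc_sigma))
  invisible(x)
}

#' Exponential update of one class mean
#'
#' Replaces the stored class mean by the convex combination
#' `(1 - uc_mu) * mu(t-1) + uc_mu * x(t)`, leaving the other class untouched,
#' and refreshes the hyperplane.
#'
#' @param model An `lda_model`.
#' @param x New feature vector.
#' @param class_id Class of the new sample, 1 or 2.
#' @param uc_mu Update coefficient in `[0, 1]`.
#' @param refresh Recompute `w` and `b` afterwards (default `TRUE`); the
#'   streaming updater defers the refresh to once per trial pair.
#' @return The updated `lda_model`.
#' @export
update_mean <- function(model, x, class_id, uc_mu, refresh = TRUE) {
  stopifnot(inherits(model, "lda_model"))
  check_fraction(uc_mu, "uc_mu")
  if (!class_id %in% c(1, 2)) abort_bad("`class_id` must be 1 or 2.")
  x <- as.numeric(x)
  if (length(x) != length(model$w) || any(!is.finite(x))) {
    abort_bad("`x` must be a finite vector of the model's dimensionality.")
  }
  field <- if (class_id == 1) "mu1" else "mu2"
  model[[field]] <- (1 - uc_mu) * model[[field]] + uc_mu * x
  if (refresh) model <- refresh_hyperplane(model)
  model
}

# Rank-one Woodbury step on the inverse covariance.
# B = a_coef * Sigma(t-1) + u_coef * d d', with d = x - mu_class(t-1);
# returns B^-1 from Sigma(t-1)^-1 without forming or inverting B.
# Exploits the symmetry of Sigma^-1 so the result is symmetric by construction.
woodbury_step <- function(sigma_inv, d, a_coef, u_coef) {
  a_inv <- sigma_inv / a_coef
  v <- drop(a_inv %*% d)
  denom <- 1 + u_coef * sum(d * v)
  if (!is.finite(denom) || abs(denom) < .Machine$double.eps) {
    abort_bad("degenerate covariance update: the Woodbury scalar (I + V'A^-1 U) is numerically zero.")
  }
  a_inv - (u_coef / denom) * tcrossprod(v)
}

#' Rank-one update of the common covariance and its inverse
#'
#' Applies the single-sample covariance update
#' `Sigma(t) = (1 - uc_sigma) * Sigma(t-1) + uc_sigma/(N-1) * d d'` with
#' `d = x - mu_class(t-1)`, and obtains `Sigma(t)^-1` directly from
#' `Sigma(t-1)^-1` via the Woodbury identity for a rank-one correction —
#' no matrix is formed and inverted. The explicit `Sigma` is tracked in
#' parallel (an O(d^2) outer-product update) so the model's
#' `sigma %*% sigma_inv` invariant stays checkable.
#'
#' The published description of this updater carries an internal
#' inconsistency: the term identified as `A` in the Woodbury expansion is
#' printed with the mean coefficient `(1 - uc_mu)` although the covariance
#' recursion it expands uses `(1 - uc_sigma)`. The default here follows the
#' covariance recursion; `printed_variant = TRUE` reproduces the printed
#' coefficient (then `uc_mu` must be supplied) for side-by-side comparison.
#'
#' @inheritParams update_mean
#' @param uc_sigma Covariance update coefficient in `[0, 1)`.
#' @param n Sample count `N` entering the `1/(N-1)` scale of the rank-one
#'   term; defaults to the model's running `n_samples`.
#' @param printed_variant Use `(1 - uc_mu)` as the coefficient of the previous
#'   covariance inside the inverse update (see Details).
#' @param uc_mu Only used when `printed_variant = TRUE`.
#' @return The updated `lda_model`.
#' @export
update_covariance_woodbury <- function(model, x, class_id, uc_sigma,
                                       n = model$n_samples,
                                       refresh = TRUE,
                                       printed_variant = FALSE,
                                       uc_mu = NULL) {
  stopifnot(inherits(model, "lda_model"))
  check_fraction(uc_sigma, "uc_sigma", closed_upper = FALSE)
  if (!class_id %in% c(1, 2)) abort_bad("`class_id` must be 1 or 2.")
  if (!is_number(n) || n < 2) abort_bad("`n` must be a sample count >= 2.")
  x <- as.numeric(x)
  if (length(x) != length(model$w) || any(!is.finite(x))) {
    abort_bad("`x` must be a finite vector of the model's dimensionality.")
  }
  if (uc_sigma > 0) {
    mu <- if (class_id == 1) model$mu1 else model$mu2
    d <- x - mu
    a_coef <- if (printed_variant) {
      if (is.null(uc_mu)) abort_bad("`printed_variant = TRUE` requires `uc_mu`.")
      check_fraction(uc_mu, "uc_mu", closed_upper = FALSE)
      1 - uc_mu
    } else {
      1 - uc_sigma
    }
    u_coef <- uc_sigma / (n - 1)
    model$sigma_inv <- woodbury_step(model$sigma_inv, d, a_coef, u_coef)
    model$sigma <- (1 - uc_sigma) * model$sigma + u_coef * tcrossprod(d)
    model$update_count <- model$update_count + 1L
    if (model$update_count %% 50L == 0L) {
      # numerical hygiene: re-impose exact symmetry periodically
      model$sigma_inv <- (model$sigma_inv + t(model$sigma_inv)) / 2
      model$sigma <- (model$sigma + t(model$sigma)) / 2
    }
  }
  if (refresh) model <- refresh_hyperplane(model)
  model
}

# Stream all windows of one trial through the single-sample updates.
# Covariance first (it uses the pre-update mean), then the mean, then N += 1.
adapt_windows <- function(model, Xw, class_id, uc) {
  for (i in seq_len(nrow(Xw))) {
    x <- Xw[i, ]
    model <- update_covariance_woodbury(
      model, x, class_id, uc$uc_sigma,
      n = model$n_samples, refresh = FALSE
    )
    model <- update_mean(model, x, class_id, uc$uc_mu, refresh = FALSE)
    model$n_samples <- model$n_samples + 1L
    key <- as.character(class_id)
    model$class_counts[[key]] <- model$class_counts[[key]] + 1L
  }
  model
}

#' Adaptive update from one new trial of each class
#'
#' Once the online stream has produced one completed trial per class, the
#' model is updated with their window-level feature vectors and the
#' hyperplane is refreshed once. In the default `"per-window"` mode the
#' single-sample mean and covariance updates are iterated over every window of
#' the class-1 trial in time order, then every window of the class-2 trial;
#' this respects the rank-one form of the covariance recursion while matching
#' the trial-pair update cadence of a closed-loop session. The alternative
#' `"trial-mean"` mode condenses each trial to its mean feature vector and
#' applies one update per trial, for sensitivity analyses.
#'
#' @param model An `lda_model`.
#' @param new_trial_class1,new_trial_class2 [feature_matrix] objects holding
#'   the windows of exactly one trial of class 1 and class 2 respectively.
#' @param uc A [uc_pair()] (or length-2 numeric `(uc_mu, uc_sigma)`).
#' @param mode `"per-window"` (default) or `"trial-mean"`.
#' @return The updated `lda_model`, with `n_samples` incremented by the number
#'   of samples incorporated and `w`, `b` refreshed.
#' @export
update_on_trial_pair <- function(model, new_trial_class1, new_trial_class2,
                                 uc, mode = c("per-window", "trial-mean")) {
  stopifnot(inherits(model, "lda_model"))
  mode <- match.arg(mode)
  uc <- as_uc_pair(uc)
  check_single_trial <- function(fm, class_id) {
    stopifnot(inherits(fm, "feature_matrix"))
    if (nrow(fm$X) == 0L) abort_bad("empty trial supplied to the updater.")
    if (length(unique(fm$window_trial)) != 1L) {
      abort_bad("each feature matrix must hold the windows of exactly one trial.")
    }
    if (any(fm$window_label != class_id)) {
      abort_bad(sprintf("trial labelled for class %d does not match its slot.", class_id))
    }
    ord <- order(fm$window_time)
    fm$X[ord, , drop = FALSE]
  }
  X1 <- check_single_trial(new_trial_class1, 1L)
  X2 <- check_single_trial(new_trial_class2, 2L)
  if (mode == "trial-mean") {
    X1 <- matrix(colMeans(X1), nrow = 1L)
    X2 <- matrix(colMeans(X2), nrow = 1L)
  }
  model <- adapt_windows(model, X1, 1L, uc)
  model <- adapt_windows(model, X2, 2L, uc)
  refresh_hyperplane(model)
}
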