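#' Battery-feedback trajectory for one trial
#'
#' Integrates the closed-loop visual feedback: at every tick the battery fill
#' moves by an amount proportional to `p - 0.5`, where `p` is the decoder's
#' probability for the cued class, scaled so that `p == 1` fills the battery in
#' exactly `timeout` seconds; the fill is floored at zero and the trial ends
#' when the battery is full or the timeout elapses.
#'
#' @param p_cue Numeric vector of per-tick cued-class probabilities.
#' @param tick Feedback update interval in seconds (default 0.05).
#' @param timeout Battery capacity / trial timeout in seconds (default 5).
#' @return A list with `level` (fill trajectory in `[0, 1]` per tick actually
#'   played), `battery_time` (seconds to full, or `NA` on timeout), and
#'   `full` (logical).
#' @export
simulate_battery <- function(p_cue, tick = 0.05, timeout = 5) {
  if (!is_number(tick) || tick <= 0) abort_bad("`tick` must be positive.")
  if (!is_number(timeout) || timeout <= 0) abort_bad("`timeout` must be positive.")
  level <- 0
  levels <- numeric(0)
  battery_time <- NA_real_
  elapsed <- 0
  for (p in p_cue) {
    elapsed <- elapsed + tick
    if (elapsed > timeout + 1e-9) break
    level <- max(0, level + 2 * (p - 0.5) * tick / timeout)
    levels <- c(levels, level)
    if (level >= 1 - 1e-9) {
      battery_time <- elapsed
      break
    }
  }
  list(level = levels, battery_time = battery_time, full = !is.na(battery_time))
}

#' Classify one replayed trial
#'
#' Computes the decoder's probability of the cued class for every sliding
#' window of the trial, averages them, and labels the trial correct when the
#' mean is strictly above the 0.5 chance level (a mean of exactly 0.5 counts
#' as incorrect). The per-tick classifier output (sign of the decision value)
#' is compared against the cue to yield the control fraction that underlies
#' BCI control performance, and the battery dynamics are integrated over the
#' same window sequence.
#'
#' @param model An `lda_model`.
#' @param trial_features A [feature_matrix] holding the windows of one trial.
#' @param cued_class The cued class for the trial, 1 or 2.
#' @param tick Feedback interval in seconds used for the battery dynamics
#'   (default 0.05, matching the replay window step).
#' @param timeout Battery capacity in seconds (default 5).
#' @return A one-row tibble: `trial_id`, `cued_class`, `n_windows`,
#'   `mean_probability` (of the cue), `correct`, `control_fraction`,
#'   `battery_time`, `battery_full`.
#' @export
classify_trial <- function(model, trial_features, cued_class,
                           tick = 0.05, timeout = 5) {
  stopifnot(inherits(model, "lda_model"), inherits(trial_features, "feature_matrix"))
  if (!cued_class %in% c(1, 2)) abort_bad("`cued_class` must be 1 or 2.")
  if (nrow(trial_features$X) == 0L) abort_bad("trial has no windows to classify.")
  ord <- order(trial_features$window_time)
  X <- trial_features$X[ord, , drop = FALSE]
  d <- decision(model, X)
  p2 <- stats::plogis(d)
  p_cue <- if (cued_class == 2) p2 else 1 - p2
  # classifier output per tick: strict sign rule, D == 0 never matches the cue
  match <- if (cued_class == 2) d > 0 else d < 0
  bat <- simulate_battery(p_cue, tick = tick, timeout = timeout)
  tibble::tibble(
    trial_id = trial_features$window_trial[1],
    cued_class = as.integer(cued_class),
    n_windows = nrow(X),
    mean_probability = mean(p_cue),
    correct = mean(p_cue) > 0.5,
    control_fraction = mean(match),
    battery_time = bat$battery_time,
    battery_full = bat$full
  )
}

#' Battery feedback across an online stream
#'
#' Replays the closed-loop feedback for every trial of an online feature
#' stream against a sequence of model states, sampling the decoder output at
#' the feedback tick interval. With `tick == timeout` each trial receives
#' exactly one tick.
#'
#' @param models A single `lda_model`, or a list of models with one entry per
#'   online trial (the model in force when that trial begins).
#' @param online A [feature_matrix] of the online stream.
#' @param tick Feedback interval in seconds.
#' @param timeout Trial timeout / battery capacity in seconds.
#' @return A list with `per_trial` (tibble of per-trial outcomes, including
#'   battery trajectories as a list-column) and `bci_control_performance`
#'   (mean control fraction across trials, percent).
#' @export
simulate_online_feedback <- function(models, online, tick = 0.05, timeout = 5) {
  stopifnot(inherits(online, "feature_matrix"))
  if (!is_number(tick) || tick <= 0) abort_bad("`tick` must be positive.")
  if (!is_number(timeout) || timeout <= 0) abort_bad("`timeout` must be positive.")
  trials <- unique(online$window_trial)
  if (inherits(models, "lda_model")) models <- list(models)
  if (length(models) == 1L) models <- rep(models, length(trials))
  if (length(models) != length(trials)) {
    abort_bad("`models` must supply one model, or one per online trial.")
  }
  rows <- purrr::map2(seq_along(trials), trials, function(i, tr) {
    fm <- features_for_trial(online, tr)
    ord <- order(fm$window_time)
    X <- fm$X[ord, , drop = FALSE]
    times <- fm$window_time[ord]
    cue <- fm$window_label[1]
    model <- models[[i]]
    # sample the window stream at the tick cadence
    n_ticks <- max(1L, floor(timeout / tick + 1e-9))
    tick_times <- (seq_len(n_ticks) - 1L) * tick
    pick <- vapply(tick_times, function(tt) {
      cand <- which(times <= tt + 1e-9)
      if (length(cand) == 0L) 1L else max(cand)
    }, integer(1))
    d <- decision(model, X[pick, , drop = FALSE])
    p2 <- stats::plogis(d)
    p_cue <- if (cue == 2) p2 else 1 - p2
    match <- if (cue == 2) d > 0 else d < 0
    bat <- simulate_battery(p_cue, tick = tick, timeout = timeout)
    n_played <- max(1L, length(bat$level))
    tibble::tibble(
      trial_id = tr,
      cued_class = as.integer(cue),
      n_ticks = n_played,
      control_fraction = mean(match[seq_len(n_played)]),
      battery_time = bat$battery_time,
      battery_full = bat$full,
      battery_level = list(bat$level)
    )
  })
  per_trial <- dplyr::bind_rows(rows)
  list(
    per_trial = per_trial,
    bci_control_performance = 100 * mean(per_trial$control_fraction)
  )
}

new_replay_result <- function(per_trial, classifier_mode, uc = NULL) {
  n1 <- sum(per_trial$cued_class == 1L)
  n2 <- sum(per_trial$cued_class == 2L)
  pa1 <- if (n1 > 0) 100 * mean(per_trial$correct[per_trial$cued_class == 1L]) else NA_real_
  pa2 <- if (n2 > 0) 100 * mean(per_trial$correct[per_trial$cued_class == 2L]) else NA_real_
  structure(
    list(
      per_trial = per_trial,
      pa = 100 * mean(per_trial$correct),
      pa_class1 = pa1,
      pa_class2 = pa2,
      bias = abs(pa1 - pa2),
      bci_control_performance = 100 * mean(per_trial$control_fraction),
      classifier_mode = classifier_mode,
      uc = uc
    ),
    class = "replay_result"
  )
}

#' @export
print.replay_result <- function(x, ...) {
  cat(sprintf("<replay_result> %s classifier, %d online trials\n",
              x$classifier_mode, nrow(x$per_trial)))
  if (!is.null(x$uc)) {
    cat(sprintf("  uc_mu = %g, uc_sigma = %g\n", x$uc$uc_mu, x$uc$uc_sigma))
  }
  cat(sprintf("  PA = %.1f%% (class 1: %.1f%%, class 2: %.1f%%), bias = %.1f\n",
              x$pa, x$pa_class1, x$pa_class2, x$bias))
  cat(sprintf("  BCI control performance = %.1f%%\n", x$bci_control_performance))
  invisible(x)
}

#' Tidiers for replay results
#'
#' @param x A `replay_result`.
#' @param ... Unused.
#' @return `tidy()`: the per-trial outcome tibble; `glance()`: a one-row
#'   summary with `pa`, per-class PAs, `bias` and `bci_control_performance`.
#' @export
tidy.replay_result <- function(x, ...) x$per_trial

#' @rdname tidy.replay_result
#' @export
glance.replay_result <- function(x, ...) {
  tibble::tibble(
    classifier_mode = x$classifier_mode,
    uc_mu = if (is.null(x$uc)) NA_real_ else x$uc$uc_mu,
    uc_sigma = if (is.null(x$uc)) NA_real_ else x$uc$uc_sigma,
    n_trials = nrow(x$per_trial),
    pa = x$pa,
    pa_class1 = x$pa_class1,
    pa_class2 = x$pa_class2,
    bias = x$bias,
    bci_control_performance = x$bci_control_performance
  )
}

online_trial_sequence <- function(online) {
  trials <- unique(online$window_trial)
  trials[order(trials)]
}

#' Replay an online stream against a frozen (static) classifier
#'
#' Trains once on the offline features and classifies every online trial with
#' the frozen model, reproducing the open-loop evaluation used to compute the
#' static predicted accuracy (PA).
#'
#' @param offline A [feature_matrix] of offline (calibration) windows covering
#'   both classes.
#' @param online A [feature_matrix] of the online stream, in acquisition
#'   order.
#' @param regularization Shrinkage passed to [train_lda()].
#' @param tick,timeout Battery feedback parameters (seconds).
#' @return A `replay_result`.
#' @export
replay_static <- function(offline, online, regularization = 1e-3,
                          tick = 0.05, timeout = 5) {
  stopifnot(inherits(offline, "feature_matrix"), inherits(online, "feature_matrix"))
  trials <- online_trial_sequence(online)
  if (length(trials) == 0L) abort_bad("the online stream holds no trials.")
  model <- train_lda(offline, regularization = regularization)
  per_trial <- dplyr::bind_rows(purrr::map(trials, function(tr) {
    fm <- features_for_trial(online, tr)
    classify_trial(model, fm, fm$window_label[1], tick = tick, timeout = timeout)
  }))
  new_replay_result(per_trial, "static")
}

#' Replay an online stream against an adaptive classifier
#'
#' Identical to [replay_static()] except that the model is updated via
#' [update_on_trial_pair()] every time one new trial of each class has
#' completed. Each trial is classified by the model version in force when it
#' begins, so no trial's outcome depends on its own data or on later trials.
#' With `uc = uc_pair(0, 0)` the result matches [replay_static()] exactly,
#' trial by trial.
#'
#' @inheritParams replay_static
#' @param uc A [uc_pair()] (or length-2 numeric `(uc_mu, uc_sigma)`).
#' @param update_mode Update granularity, `"per-window"` (default) or
#'   `"trial-mean"`; see [update_on_trial_pair()].
#' @return A `replay_result`.
#' @export
replay_adaptive <- function(offline, online, uc, regularization = 1e-3,
                            update_mode = c("per-window", "trial-mean"),
                            tick = 0.05, timeout = 5) {
  stopifnot(inherits(offline, "feature_matrix"), inherits(online, "feature_matrix"))
  uc <- as_uc_pair(uc)
  update_mode <- match.arg(update_mode)
  trials <- online_trial_sequence(online)
  if (length(trials) == 0L) abort_bad("the online stream holds no trials.")
  model <- train_lda(offline, regularization = regularization)
  pending <- list(`1` = list(), `2` = list())
  rows <- vector("list", length(trials))
  for (i in seq_along(trials)) {
    fm <- features_for_trial(online, trials[i])
    cue <- fm$window_label[1]
    rows[[i]] <- classify_trial(model, fm, cue, tick = tick, timeout = timeout)
    key <- as.character(cue)
    pending[[key]] <- c(pending[[key]], list(fm))
    while (length(pending$`1`) > 0L && length(pending$`2`) > 0L) {
      model <- update_on_trial_pair(
        model, pending$`1`[[1]], pending$`2`[[1]], uc, mode = update_mode
      )
      pending$`1` <- pending$`1`[-1]
      pending$`2` <- pending$`2`[-1]
    }
  }
  new_replay_result(dplyr::bind_rows(rows), "adaptive", uc = uc)
}
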