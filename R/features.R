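#' Window-by-feature matrix of spectral features
#'
#' Holds one log band power feature vector per sliding window, together with
#' the bookkeeping that maps every window back to its parent trial. Built by
#' [extract_psd_features()]; the constructor is exported so small fixtures can
#' be assembled directly.
#'
#' @param X Numeric matrix, windows x features.
#' @param window_trial Integer parent-trial index per window.
#' @param window_label Integer class label (1 or 2) per window, inherited from
#'   the parent trial.
#' @param window_time Window start time in seconds relative to trial onset.
#' @param window_phase Character `"offline"`/`"online"` per window.
#' @param freq_bins Optional tibble of bin edges (`low`, `high`, in Hz).
#' @param channels_used Optional character vector of channel identifiers.
#' @param log_power Logical; whether `X` holds log-transformed power.
#'
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(X, window_trial, window_label,
                           window_time = NULL, window_phase = NULL,
                           freq_bins = NULL, channels_used = NULL,
                           log_power = TRUE) {
  X <- as.matrix(X)
  nw <- nrow(X)
  window_trial <- as.integer(window_trial)
  window_label <- as.integer(window_label)
  if (length(window_trial) != nw || length(window_label) != nw) {
    abort_bad("`window_trial` and `window_label` must have one entry per window.")
  }
  if (!all(window_label %in% c(1L, 2L))) abort_bad("window labels must be 1 or 2.")
  if (any(!is.finite(X))) abort_bad("feature matrix contains non-finite entries.")
  # a window's label must be constant within its parent trial
  lab_by_trial <- tapply(window_label, window_trial, function(l) length(unique(l)))
  if (any(lab_by_trial > 1L)) {
    abort_bad("windows of one trial carry inconsistent class labels.")
  }
  if (is.null(window_time)) window_time <- rep(NA_real_, nw)
  if (is.null(window_phase)) window_phase <- rep("offline", nw)
  structure(
    list(
      X = X,
      window_trial = window_trial,
      window_label = window_label,
      window_time = as.numeric(window_time),
      window_phase = window_phase,
      freq_bins = freq_bins,
      channels_used = channels_used,
      log_power = isTRUE(log_power)
    ),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d windows x %d features (%s power)\n",
              nrow(x$X), ncol(x$X), if (x$log_power) "log" else "linear"))
  cat(sprintf("  trials: %d | classes: 1 -> %d, 2 -> %d windows\n",
              length(unique(x$window_trial)),
              sum(x$window_label == 1L), sum(x$window_label == 2L)))
  invisible(x)
}

#' Subset a feature matrix by window
#'
#' @param x A [feature_matrix].
#' @param idx Logical or integer index over windows.
#' @return A [feature_matrix] restricted to the selected windows.
#' @export
subset_windows <- function(x, idx) {
  stopifnot(inherits(x, "feature_matrix"))
  feature_matrix(
    X = x$X[idx, , drop = FALSE],
    window_trial = x$window_trial[idx],
    window_label = x$window_label[idx],
    window_time = x$window_time[idx],
    window_phase = x$window_phase[idx],
    freq_bins = x$freq_bins,
    channels_used = x$channels_used,
    log_power = x$log_power
  )
}

#' Split a feature matrix by experiment phase
#'
#' @param x A [feature_matrix].
#' @return A named list with `offline` and `online` feature matrices.
#' @export
split_by_phase <- function(x) {
  stopifnot(inherits(x, "feature_matrix"))
  list(
    offline = subset_windows(x, x$window_phase == "offline"),
    online = subset_windows(x, x$window_phase == "online")
  )
}

features_for_trial <- function(x, trial) {
  subset_windows(x, x$window_trial == trial)
}

#' Notch filter, channel exclusion and common average reference
#'
#' Reproduces the standard EEG preprocessing chain ahead of spectral feature
#' extraction: drop the listed channels (e.g. the reference and mastoids),
#' apply a zero-phase band-stop (notch) filter around the line frequency, then
#' re-reference every channel to the common average of the retained channels.
#'
#' @param raw An [eeg_epochs] object.
#' @param notch_hz Notch centre frequency in Hz (default 50, European mains).
#'   Use `NULL` to skip the notch.
#' @param exclude_channels Character vector of channel names to drop before
#'   filtering and re-referencing.
#' @param notch_halfwidth Half-width of the stop band in Hz (default 2).
#' @return An [eeg_epochs] object with the retained, filtered, re-referenced
#'   channels.
#' @export
preprocess <- function(raw, notch_hz = 50, exclude_channels = character(),
                       notch_halfwidth = 2) {
  stopifnot(inherits(raw, "eeg_epochs"))
  fs <- raw$sampling_rate
  if (!is.null(notch_hz)) {
    if (!is_number(notch_hz) || notch_hz + notch_halfwidth >= fs / 2) {
      abort_bad("`notch_hz` (plus half-width) must lie below the Nyquist frequency.")
    }
  }
  exclude_channels <- as.character(exclude_channels)
  missing <- setdiff(exclude_channels, raw$channel_names)
  if (length(missing) > 0L) {
    abort_bad("unknown channels in `exclude_channels`: ",
              paste(missing, collapse = ", "))
  }
  keep <- !(raw$channel_names %in% exclude_channels)
  if (!any(keep)) abort_bad("excluding all channels leaves nothing to analyse.")

  data <- raw$data[, keep, , drop = FALSE]
  nt <- dim(data)[1]; nc <- dim(data)[2]

  if (!is.null(notch_hz)) {
    band <- c(notch_hz - notch_halfwidth, notch_hz + notch_halfwidth) / (fs / 2)
    filt <- signal::butter(2, band, type = "stop")
    for (t in seq_len(nt)) {
      for (ch in seq_len(nc)) {
        data[t, ch, ] <- signal::filtfilt(filt, data[t, ch, ])
      }
    }
  }

  # common average reference over the retained channels
  ns <- dim(data)[3]
  for (t in seq_len(nt)) {
    mat <- matrix(data[t, , ], nc, ns)
    data[t, , ] <- sweep(mat, 2, colMeans(mat), check.margin = FALSE)
  }

  eeg_epochs(
    data = data,
    labels = raw$labels,
    sampling_rate = fs,
    channel_names = raw$channel_names[keep],
    phase = raw$phase,
    trial_order = raw$trial_order,
    ground_truth = raw$ground_truth
  )
}

#' Sliding-window log band power features
#'
#' Splits every trial into sliding windows and computes, per window and
#' channel, a Hann-tapered one-sided periodogram aggregated into contiguous
#' frequency bins across `band`. Features are ordered channel-major (all bins
#' of channel 1, then channel 2, ...) and log-transformed by default, the
#' standard choice ahead of an LDA on spectral features.
#'
#' The number of windows per trial is
#' `floor((duration - window_len) / window_step) + 1`.
#'
#' @param epochs An [eeg_epochs] object (typically after [preprocess()]).
#' @param window_len Window length in seconds (default 0.5).
#' @param window_step Step between window onsets in seconds (default 0.05).
#' @param band Two-element numeric, analysis band (low, high) in Hz
#'   (default `c(1, 70)`).
#' @param bin_width Width of each aggregated frequency bin in Hz (default 2).
#' @param log_power Log-transform the binned power (default `TRUE`).
#' @return A [feature_matrix] with
#'   `n_channels * ceiling((band[2]-band[1])/bin_width)` features per window.
#' @export
extract_psd_features <- function(epochs, window_len = 0.5, window_step = 0.05,
                                 band = c(1, 70), bin_width = 2,
                                 log_power = TRUE) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  fs <- epochs$sampling_rate
  ns <- n_samples_of(epochs)
  duration <- ns / fs
  if (!is_number(window_len) || window_len <= 0 || window_len > duration + 1e-9) {
    abort_bad("`window_len` must be positive and no longer than the trial.")
  }
  if (!is_number(window_step) || window_step <= 0) {
    abort_bad("`window_step` must be positive.")
  }
  if (length(band) != 2L || band[1] < 0 || band[2] <= band[1] ||
      band[2] >= fs / 2) {
    abort_bad("`band` must satisfy 0 <= low < high < sampling_rate/2.")
  }
  if (!is_number(bin_width) || bin_width <= 0) abort_bad("`bin_width` must be positive.")

  wl <- round(window_len * fs)
  # window onsets live on the continuous time grid k * window_step; each onset
  # is rounded to the nearest sample, so the window count matches
  # floor((duration - window_len) / window_step) + 1 at any sampling rate
  nw <- as.integer(floor((duration - window_len) / window_step + 1e-9) + 1L)
  if (nw < 1L) abort_bad("window longer than trial.")
  starts <- pmin(round((seq_len(nw) - 1L) * window_step * fs), ns - wl)

  # Hann taper; one-sided periodogram scaling
  n0 <- seq_len(wl) - 1L
  h <- 0.5 - 0.5 * cos(2 * pi * n0 / (wl - 1L))
  scale <- fs * sum(h^2)
  nfreq <- wl %/% 2L + 1L
  freqs <- (seq_len(nfreq) - 1L) * fs / wl

  n_bins <- as.integer(ceiling((band[2] - band[1]) / bin_width))
  lo <- band[1] + (seq_len(n_bins) - 1L) * bin_width
  hi <- pmin(lo + bin_width, band[2])
  binmat <- matrix(0, n_bins, nfreq)
  for (j in seq_len(n_bins)) {
    inbin <- if (j == n_bins) freqs >= lo[j] & freqs <= hi[j] else
      freqs >= lo[j] & freqs < hi[j]
    if (!any(inbin)) {
      abort_bad(sprintf(
        "frequency bin [%g, %g) Hz holds no spectral line; use a longer window or wider bins.",
        lo[j], hi[j]
      ))
    }
    binmat[j, inbin] <- 1 / sum(inbin)
  }

  nt <- n_trials(epochs)
  nc <- n_channels_of(epochs)
  d <- nc * n_bins
  X <- matrix(NA_real_, nt * nw, d)
  idx <- outer(seq_len(wl), starts, "+")

  for (t in seq_len(nt)) {
    for (ch in seq_len(nc)) {
      seg <- matrix(epochs$data[t, ch, ][idx], wl, nw) * h
      sp <- stats::mvfft(seg)
      P <- (Mod(sp[seq_len(nfreq), , drop = FALSE])^2) / scale
      if (nfreq > 2L) P[2:(nfreq - 1L), ] <- 2 * P[2:(nfreq - 1L), ]
      binned <- binmat %*% P # n_bins x nw
      rows <- (t - 1L) * nw + seq_len(nw)
      cols <- (ch - 1L) * n_bins + seq_len(n_bins)
      X[rows, cols] <- t(binned)
    }
  }

  if (log_power) X <- log(pmax(X, .Machine$double.xmin))
  colnames(X) <- as.vector(t(outer(
    epochs$channel_names, sprintf("%g-%gHz", lo, hi), paste, sep = "_"
  )))

  feature_matrix(
    X = X,
    window_trial = rep(seq_len(nt), each = nw),
    window_label = rep(epochs$labels, each = nw),
    window_time = rep((seq_len(nw) - 1L) * window_step, nt),
    window_phase = rep(epochs$phase, each = nw),
    freq_bins = tibble::tibble(low = lo, high = hi),
    channels_used = epochs$channel_names,
    log_power = log_power
  )
}
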