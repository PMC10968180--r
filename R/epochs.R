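#' Epoched multichannel EEG container
#'
#' Bundles per-trial signal blocks with their class labels and acquisition
#' metadata. The signal is stored as a dense `trials x channels x samples`
#' array in microvolt-scale units; everything downstream (preprocessing,
#' feature extraction, replay) consumes this container.
#'
#' @param data Numeric array, `trials x channels x samples`.
#' @param labels Integer vector of per-trial class labels, values 1 or 2.
#' @param sampling_rate Sampling rate in Hz.
#' @param channel_names Character vector of channel identifiers; defaults to
#'   `"ch01"`, `"ch02"`, ...
#' @param phase Character vector flagging each trial as `"offline"`
#'   (open-loop calibration data) or `"online"` (closed-loop control data).
#' @param trial_order Integer acquisition index per trial; defaults to
#'   `seq_len(n_trials)`.
#' @param ground_truth Optional tibble of per-trial generating parameters
#'   (attached by the synthetic generator so tests can build Bayes oracles).
#'
#' @return An object of class `eeg_epochs`.
#' @seealso [generate_dataset()], [preprocess()], [extract_psd_features()]
#' @export
eeg_epochs <- function(data, labels, sampling_rate,
                       channel_names = NULL,
                       phase = NULL,
                       trial_order = NULL,
                       ground_truth = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    abort_bad("`data` must be a 3-d array (trials x channels x samples).")
  }
  n_trials <- dim(data)[1]
  n_channels <- dim(data)[2]
  labels <- as.integer(labels)
  if (length(labels) != n_trials || !all(labels %in% c(1L, 2L))) {
    abort_bad("`labels` must have one entry per trial, each 1 or 2.")
  }
  if (!is_number(sampling_rate) || sampling_rate <= 0) {
    abort_bad("`sampling_rate` must be a positive number (Hz).")
  }
  if (is.null(channel_names)) {
    channel_names <- sprintf("ch%02d", seq_len(n_channels))
  }
  if (length(channel_names) != n_channels) {
    abort_bad("`channel_names` must match the channel dimension of `data`.")
  }
  if (is.null(phase)) phase <- rep("offline", n_trials)
  if (length(phase) != n_trials || !all(phase %in% c("offline", "online"))) {
    abort_bad("`phase` must be per-trial, each \"offline\" or \"online\".")
  }
  if (is.null(trial_order)) trial_order <- seq_len(n_trials)
  trial_order <- as.integer(trial_order)
  if (length(trial_order) != n_trials || anyDuplicated(trial_order) > 0L) {
    abort_bad("`trial_order` must be a permutation-free acquisition index per trial.")
  }
  structure(
    list(
      data = data,
      labels = labels,
      sampling_rate = sampling_rate,
      channel_names = as.character(channel_names),
      phase = phase,
      trial_order = trial_order,
      ground_truth = ground_truth
    ),
    class = "eeg_epochs"
  )
}

n_trials <- function(x) dim(x$data)[1]
n_channels_of <- function(x) dim(x$data)[2]
n_samples_of <- function(x) dim(x$data)[3]

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(sprintf(
    "<eeg_epochs> %d trials x %d channels x %d samples @ %g Hz\n",
    n_trials(x), n_channels_of(x), n_samples_of(x), x$sampling_rate
  ))
  cat(sprintf("  phases : offline %d | online %d\n",
              sum(x$phase == "offline"), sum(x$phase == "online")))
  cat(sprintf("  classes: 1 -> %d trials | 2 -> %d trials\n",
              sum(x$labels == 1L), sum(x$labels == 2L)))
  if (!is.null(x$ground_truth)) cat("  ground-truth generating parameters attached\n")
  invisible(x)
}

#' Tidy per-trial metadata of an epochs container
#'
#' @param x An [eeg_epochs] object.
#' @param ... Unused.
#' @return A tibble with one row per trial: `trial`, `trial_order`, `phase`,
#'   `label`, joined with the generator's ground-truth columns when present.
#' @export
tidy.eeg_epochs <- function(x, ...) {
  out <- tibble::tibble(
    trial = seq_len(n_trials(x)),
    trial_order = x$trial_order,
    phase = x$phase,
    label = x$labels
  )
  if (!is.null(x$ground_truth)) {
    out <- dplyr::left_join(out, x$ground_truth, by = "trial")
  }
  out
}

#' Subset an epochs container by trial
#'
#' @param x An [eeg_epochs] object.
#' @param trials Integer vector of trial indices to keep.
#' @return An [eeg_epochs] object with the selected trials.
#' @export
subset_trials <- function(x, trials) {
  stopifnot(inherits(x, "eeg_epochs"))
  trials <- as.integer(trials)
  if (any(trials < 1L | trials > n_trials(x))) abort_bad("trial index out of range.")
  gt <- x$ground_truth
  if (!is.null(gt)) {
    gt <- gt[match(trials, gt$trial), , drop = FALSE]
    gt$trial <- seq_along(trials)
  }
  eeg_epochs(
    data = x$data[trials, , , drop = FALSE],
    labels = x$labels[trials],
    sampling_rate = x$sampling_rate,
    channel_names = x$channel_names,
    phase = x$phase[trials],
    trial_order = x$trial_order[trials],
    ground_truth = gt
  )
}
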