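#' Plain-text serialization of containers
#'
#' Datasets, feature matrices and models are persisted as a small directory
#' holding a JSON metadata file plus CSV arrays — a portable, diff-able
#' container with the same logical layout (data / labels / phase / meta) used
#' throughout the package. Round-trips preserve values to full double
#' precision (numbers are serialized with 17 significant digits).
#'
#' @name adaptlda-io
NULL

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
}

#' Write / read an epochs container
#'
#' @param epochs An [eeg_epochs] object.
#' @param dir Directory to create (or overwrite) with `meta.json` and
#'   `signals.csv`.
#' @return `write_epochs()` returns `dir` invisibly; `read_epochs()` returns
#'   the reconstructed [eeg_epochs].
#' @rdname epochs-io
#' @export
write_epochs <- function(epochs, dir) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nt <- n_trials(epochs); nc <- n_channels_of(epochs); ns <- n_samples_of(epochs)
  meta <- list(
    container = "adaptlda-epochs", version = 1L,
    n_trials = nt, n_channels = nc, n_samples = ns,
    sampling_rate = epochs$sampling_rate,
    channel_names = epochs$channel_names,
    labels = epochs$labels,
    phase = epochs$phase,
    trial_order = epochs$trial_order,
    ground_truth = if (is.null(epochs$ground_truth)) NULL else
      as.data.frame(epochs$ground_truth)
  )
  write_json_file(meta, file.path(dir, "meta.json"))
  # one row per (trial, channel): samples across columns
  flat <- matrix(aperm(epochs$data, c(3, 2, 1)), nrow = nt * nc, byrow = TRUE)
  df <- tibble::as_tibble(flat, .name_repair = ~ sprintf("s%d", seq_len(ns)))
  df <- dplyr::bind_cols(
    tibble::tibble(trial = rep(seq_len(nt), each = nc),
                   channel = rep(seq_len(nc), nt)),
    df
  )
  readr::write_csv(df, file.path(dir, "signals.csv"))
  invisible(dir)
}

#' @param dir Directory previously written by [write_epochs()].
#' @rdname epochs-io
#' @export
read_epochs <- function(dir) {
  if (!file.exists(file.path(dir, "meta.json"))) {
    abort_bad("no meta.json found in `dir`; not an adaptlda epochs container.")
  }
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  if (!identical(meta$container, "adaptlda-epochs")) {
    abort_bad("`dir` is not an adaptlda epochs container.")
  }
  df <- readr::read_csv(file.path(dir, "signals.csv"),
                        show_col_types = FALSE, progress = FALSE)
  nt <- meta$n_trials; nc <- meta$n_channels; ns <- meta$n_samples
  data <- array(0, dim = c(nt, nc, ns))
  vals <- as.matrix(df[, -(1:2), drop = FALSE])
  for (r in seq_len(nrow(df))) {
    data[df$trial[r], df$channel[r], ] <- vals[r, ]
  }
  gt <- meta$ground_truth
  if (!is.null(gt)) gt <- tibble::as_tibble(gt)
  eeg_epochs(
    data = data,
    labels = meta$labels,
    sampling_rate = meta$sampling_rate,
    channel_names = meta$channel_names,
    phase = meta$phase,
    trial_order = meta$trial_order,
    ground_truth = gt
  )
}

#' Write / read a feature matrix
#'
#' @param features A [feature_matrix].
#' @param dir Directory to create with `meta.json`, `X.csv` and
#'   `windows.csv`.
#' @return `write_features()` returns `dir` invisibly; `read_features()`
#'   returns the reconstructed [feature_matrix].
#' @rdname features-io
#' @export
write_features <- function(features, dir) {
  stopifnot(inherits(features, "feature_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(
    container = "adaptlda-features", version = 1L,
    n_windows = nrow(features$X), n_features = ncol(features$X),
    feature_names = colnames(features$X),
    channels_used = features$channels_used,
    log_power = features$log_power,
    freq_bins = if (is.null(features$freq_bins)) NULL else
      as.data.frame(features$freq_bins)
  )
  write_json_file(meta, file.path(dir, "meta.json"))
  readr::write_csv(tibble::as_tibble(features$X, .name_repair = "minimal"),
                   file.path(dir, "X.csv"))
  readr::write_csv(
    tibble::tibble(
      window_trial = features$window_trial,
      window_label = features$window_label,
      window_time = features$window_time,
      window_phase = features$window_phase
    ),
    file.path(dir, "windows.csv")
  )
  invisible(dir)
}

#' @param dir Directory previously written by [write_features()].
#' @rdname features-io
#' @export
read_features <- function(dir) {
  if (!file.exists(file.path(dir, "meta.json"))) {
    abort_bad("no meta.json found in `dir`; not an adaptlda features container.")
  }
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  if (!identical(meta$container, "adaptlda-features")) {
    abort_bad("`dir` is not an adaptlda features container.")
  }
  X <- as.matrix(readr::read_csv(file.path(dir, "X.csv"),
                                 show_col_types = FALSE, progress = FALSE))
  if (!is.null(meta$feature_names)) colnames(X) <- meta$feature_names
  w <- readr::read_csv(file.path(dir, "windows.csv"),
                       show_col_types = FALSE, progress = FALSE)
  fb <- meta$freq_bins
  feature_matrix(
    X = X,
    window_trial = w$window_trial,
    window_label = w$window_label,
    window_time = w$window_time,
    window_phase = w$window_phase,
    freq_bins = if (is.null(fb)) NULL else tibble::as_tibble(fb),
    channels_used = meta$channels_used,
    log_power = meta$log_power
  )
}

#' Write / read a fitted LDA model
#'
#' @param model An `lda_model`.
#' @param path JSON file path.
#' @return `write_lda_model()` returns `path` invisibly; `read_lda_model()`
#'   the reconstructed model.
#' @rdname model-io
#' @export
write_lda_model <- function(model, path) {
  stopifnot(inherits(model, "lda_model"))
  obj <- list(
    container = "adaptlda-model", version = 1L,
    mu1 = model$mu1, mu2 = model$mu2,
    sigma = as.vector(model$sigma), sigma_inv = as.vector(model$sigma_inv),
    d = length(model$mu1),
    n_samples = model$n_samples,
    class_counts = as.list(model$class_counts),
    regularization = model$regularization
  )
  write_json_file(obj, path)
  invisible(path)
}

#' @param path JSON file written by [write_lda_model()].
#' @rdname model-io
#' @export
read_lda_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$container, "adaptlda-model")) {
    abort_bad("`path` is not an adaptlda model file.")
  }
  d <- obj$d
  new_lda_model(
    mu1 = obj$mu1, mu2 = obj$mu2,
    sigma = matrix(obj$sigma, d, d),
    sigma_inv = matrix(obj$sigma_inv, d, d),
    n_samples = obj$n_samples,
    class_counts = unlist(obj$class_counts),
    regularization = obj$regularization
  )
}
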