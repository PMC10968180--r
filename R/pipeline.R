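#' Experiment configuration
#'
#' Assembles and validates the configuration of an end-to-end run:
#' generation (or import), preprocessing, feature extraction, classifier,
#' adaptation and replay settings. The default values pin the conventional
#' parameters of a closed-loop syllable-imagery session: 50 Hz notch, common
#' average reference, 1–70 Hz band in 2 Hz bins, 500 ms windows with a 50 ms
#' step, 5 s trials and timeout, 50 ms feedback tick, the 15-value UC lattice
#' and an 8-fold cross-validation.
#'
#' @param synth A [synth_config()] (or a plain list of its fields) describing
#'   the synthetic dataset; ignored when `input_dir` is given.
#' @param input_dir Optional epochs container (see [read_epochs()]) replacing
#'   the synthetic generation stage.
#' @param preprocessing List: `notch_hz`, `notch_halfwidth`,
#'   `exclude_channels`.
#' @param features List: `window_len`, `window_step`, `band`, `bin_width`,
#'   `log_power`.
#' @param classifier List: `regularization`, `cv_folds`.
#' @param adaptation List: `uc_mu`, `uc_sigma`, `update_mode`, and optionally
#'   `grid_mu` / `grid_sigma` to request a grid search.
#' @param replay List: `tick`, `timeout`.
#' @param seed Integer seed governing every stochastic stage.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(synth = synth_config(),
                              input_dir = NULL,
                              preprocessing = list(),
                              features = list(),
                              classifier = list(),
                              adaptation = list(),
                              replay = list(),
                              seed = 1L) {
  defaults <- list(
    preprocessing = list(notch_hz = 50, notch_halfwidth = 2,
                         exclude_channels = character()),
    features = list(window_len = 0.5, window_step = 0.05,
                    band = c(1, 70), bin_width = 2, log_power = TRUE),
    classifier = list(regularization = 1e-3, cv_folds = 8),
    adaptation = list(uc_mu = 0.4 * 2^-6, uc_sigma = 0.4 * 2^-3,
                      update_mode = "per-window",
                      grid_mu = NULL, grid_sigma = NULL),
    replay = list(tick = 0.05, timeout = 5)
  )
  merge_in <- function(base, user) {
    utils::modifyList(base, lapply(user, function(x) {
      if (is.list(x)) unlist(x) else x # YAML sequences arrive as lists
    }), keep.null = TRUE)
  }
  cfg <- list(
    synth = if (inherits(synth, "synth_config")) unclass(synth) else
      lapply(synth, function(x) if (is.list(x)) unlist(x) else x),
    input_dir = input_dir,
    preprocessing = merge_in(defaults$preprocessing, preprocessing),
    features = merge_in(defaults$features, features),
    classifier = merge_in(defaults$classifier, classifier),
    adaptation = merge_in(defaults$adaptation, adaptation),
    replay = merge_in(defaults$replay, replay),
    seed = as.integer(seed)
  )
  cfg$preprocessing$exclude_channels <-
    as.character(cfg$preprocessing$exclude_channels %||% character())
  class(cfg) <- "experiment_config"
  validate_experiment_config(cfg)
  cfg
}

validate_experiment_config <- function(cfg) {
  if (is.null(cfg$input_dir)) {
    sc <- cfg$synth
    sc$seed <- sc$seed %||% cfg$seed
    do.call(synth_config, sc)
    dur <- sc$trial_duration
    if (cfg$features$window_len > dur) {
      abort_bad("feature window is longer than the trial.")
    }
    if (cfg$features$band[2] >= sc$sampling_rate / 2) {
      abort_bad("analysis band exceeds the Nyquist frequency.")
    }
  }
  uc_pair(cfg$adaptation$uc_mu, cfg$adaptation$uc_sigma)
  check_fraction(cfg$classifier$regularization, "regularization")
  invisible(cfg)
}

#' Read / write an experiment configuration as YAML
#'
#' `parse(serialize(config))` reproduces the configuration exactly, so a
#' stored YAML file fully determines a run given its seed.
#'
#' @param config An [experiment_config()].
#' @param path YAML file path.
#' @rdname config-io
#' @return `write_config()` returns `path` invisibly; `read_config()` the
#'   parsed `experiment_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' @rdname config-io
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  experiment_config(
    synth = raw$synth,
    input_dir = raw$input_dir,
    preprocessing = raw$preprocessing,
    features = raw$features,
    classifier = raw$classifier,
    adaptation = raw$adaptation,
    replay = raw$replay,
    seed = raw$seed
  )
}

#' Run the full pipeline: generate, featurize, train, replay, optimize
#'
#' Executes the configured stages in order — dataset generation (or import),
#' preprocessing, feature extraction, static training with cross-validation,
#' static and adaptive replay, and (when a grid is configured) the UC grid
#' search — writing JSON results and a manifest into `out_dir`. With a fixed
#' configuration and seed, two runs produce identical result files.
#'
#' @param config An [experiment_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the in-memory results (`epochs`,
#'   `features`, `model`, `cv_accuracy`, `static`, `adaptive`, and `grid` /
#'   `summary` / `selection` when a grid was run).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "experiment_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  epochs <- if (!is.null(config$input_dir)) {
    if (!dir.exists(config$input_dir)) {
      abort_bad("input directory not found: ", config$input_dir)
    }
    read_epochs(config$input_dir)
  } else {
    sc <- config$synth
    sc$seed <- sc$seed %||% config$seed
    drifting <- (sc$mean_drift_rate %||% 0) > 0 || (sc$cov_drift_rate %||% 0) > 0
    cfg <- do.call(synth_config, sc)
    if (drifting) generate_drift_scenario(cfg) else generate_dataset(cfg)
  }

  pp <- config$preprocessing
  clean <- preprocess(epochs, notch_hz = pp$notch_hz,
                      exclude_channels = pp$exclude_channels,
                      notch_halfwidth = pp$notch_halfwidth)
  fe <- config$features
  feats <- extract_psd_features(clean,
                                window_len = fe$window_len,
                                window_step = fe$window_step,
                                band = fe$band, bin_width = fe$bin_width,
                                log_power = fe$log_power)
  phases <- split_by_phase(feats)
  if (nrow(phases$online$X) == 0L) abort_bad("the dataset holds no online trials.")

  cl <- config$classifier
  model <- train_lda(phases$offline, regularization = cl$regularization)
  cv <- cross_validated_accuracy(phases$offline, k = cl$cv_folds,
                                 seed = config$seed,
                                 regularization = cl$regularization)

  rp <- config$replay
  static <- replay_static(phases$offline, phases$online,
                          regularization = cl$regularization,
                          tick = rp$tick, timeout = rp$timeout)
  ad <- config$adaptation
  adaptive <- replay_adaptive(phases$offline, phases$online,
                              uc_pair(ad$uc_mu, ad$uc_sigma),
                              regularization = cl$regularization,
                              update_mode = ad$update_mode,
                              tick = rp$tick, timeout = rp$timeout)

  results <- list(
    epochs = epochs, features = feats, model = model,
    cv_accuracy = cv, static = static, adaptive = adaptive
  )

  if (!is.null(ad$grid_mu) && !is.null(ad$grid_sigma)) {
    grid <- grid_search(phases$offline, phases$online,
                        grid_mu = ad$grid_mu, grid_sigma = ad$grid_sigma,
                        regularization = cl$regularization,
                        update_mode = ad$update_mode,
                        tick = rp$tick, timeout = rp$timeout,
                        dataset_id = "run")
    summary <- aggregate_sim(list(grid))
    selection <- select_uc_pair(summary)
    results$grid <- grid
    results$summary <- summary
    results$selection <- selection
    readr::write_csv(tibble::as_tibble(grid), file.path(out_dir, "grid.csv"))
    write_json_file(as.list(selection[1, c("uc_mu", "uc_sigma")]),
                    file.path(out_dir, "selected_uc.json"))
  }

  write_config(config, file.path(out_dir, "config.yaml"))
  summary_json <- list(
    cv_accuracy = cv,
    static = as.list(glance(static)),
    adaptive = as.list(glance(adaptive))
  )
  write_json_file(summary_json, file.path(out_dir, "results.json"))
  readr::write_csv(static$per_trial, file.path(out_dir, "static_trials.csv"))
  readr::write_csv(adaptive$per_trial, file.path(out_dir, "adaptive_trials.csv"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("adaptlda")),
    seed = config$seed,
    config_hash = rlang::hash(unclass(config)),
    stages = c("generate", "preprocess", "features", "train", "cv",
               "replay_static", "replay_adaptive",
               if (!is.null(results$grid)) "grid_search"),
    results_hash = rlang::hash(summary_json)
  )
  write_json_file(manifest, file.path(out_dir, "manifest.json"))
  invisible(results)
}

#' Summarise a completed run directory
#'
#' Reads the JSON/CSV outputs of [run_pipeline()] and prints a compact summary
#' of predicted accuracy, bias and control performance; returns the parsed
#' results invisibly. Regenerating the report does not modify the run.
#'
#' @param run_dir Directory written by [run_pipeline()].
#' @return Invisibly, a list with `results`, `manifest`, and (when present)
#'   the grid tibble.
#' @export
report_run <- function(run_dir) {
  required <- file.path(run_dir, c("results.json", "manifest.json"))
  missing <- required[!file.exists(required)]
  if (length(missing) > 0L) {
    abort_bad("incomplete run; missing: ", paste(basename(missing), collapse = ", "))
  }
  results <- jsonlite::read_json(file.path(run_dir, "results.json"),
                                 simplifyVector = TRUE)
  manifest <- jsonlite::read_json(file.path(run_dir, "manifest.json"),
                                  simplifyVector = TRUE)
  cat(sprintf("Run %s (seed %d)\n", manifest$config_hash, manifest$seed))
  cat(sprintf("  offline CV accuracy : %.1f%%\n", results$cv_accuracy))
  cat(sprintf("  static   PA %.1f%% | bias %.1f | control %.1f%%\n",
              results$static$pa, results$static$bias,
              results$static$bci_control_performance))
  cat(sprintf("  adaptive PA %.1f%% | bias %.1f | control %.1f%% (uc_mu %g, uc_sigma %g)\n",
              results$adaptive$pa, results$adaptive$bias,
              results$adaptive$bci_control_performance,
              results$adaptive$uc_mu, results$adaptive$uc_sigma))
  out <- list(results = results, manifest = manifest)
  grid_path <- file.path(run_dir, "grid.csv")
  if (file.exists(grid_path)) {
    out$grid <- readr::read_csv(grid_path, show_col_types = FALSE, progress = FALSE)
    sel <- jsonlite::read_json(file.path(run_dir, "selected_uc.json"),
                               simplifyVector = TRUE)
    cat(sprintf("  grid search: selected uc_mu %g, uc_sigma %g over %d pairs\n",
                sel$uc_mu, sel$uc_sigma, nrow(out$grid)))
  }
  invisible(out)
}
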