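#' Canonical lattice of candidate update coefficients
#'
#' The candidate values span `0.4 * 2^-14` to `0.4` in increments of powers of
#' two, 15 values in total: value `k` (1-based) equals `0.4 * 2^(k - 15)`.
#' The same ladder is used for both `uc_mu` and `uc_sigma`, giving a 15 x 15
#' lattice of 225 candidate pairs.
#'
#' @param n Number of values (default 15).
#' @param top Largest value (default 0.4; the cap keeps the update speed from
#'   becoming destabilising).
#' @return A strictly increasing numeric vector of length `n`.
#' @export
uc_grid <- function(n = 15, top = 0.4) {
  if (!is_count(n)) abort_bad("`n` must be a positive integer.")
  if (!is_number(top) || top <= 0 || top > 1) abort_bad("`top` must be in (0, 1].")
  top * 2^(seq_len(n) - n)
}

#' Grid search over update-coefficient pairs for one dataset
#'
#' Runs [replay_static()] once and [replay_adaptive()] for every candidate
#' `(uc_mu, uc_sigma)` pair, and derives, per pair, the adaptive predicted
#' accuracy (PA), the modulated PA (adaptive minus static PA), the adaptive
#' bias `|PA_class1 - PA_class2|` and the modulated bias (adaptive minus
#' static bias).
#'
#' @param offline,online [feature_matrix] objects for the two phases.
#' @param grid_mu,grid_sigma Candidate values for `uc_mu` and `uc_sigma`
#'   (default: the canonical [uc_grid()]).
#' @param regularization,update_mode,tick,timeout Passed through to the replay
#'   functions.
#' @param dataset_id Optional identifier stored with the result.
#' @return A tibble of class `sim_matrices` with one row per UC pair and
#'   columns `uc_mu`, `uc_sigma`, `adaptive_pa`, `modulated_pa`,
#'   `adaptive_bias`, `modulated_bias`; the static PA and bias are attached as
#'   attributes `static_pa` and `static_bias`.
#' @export
grid_search <- function(offline, online,
                        grid_mu = uc_grid(), grid_sigma = uc_grid(),
                        regularization = 1e-3,
                        update_mode = "per-window",
                        tick = 0.05, timeout = 5,
                        dataset_id = NULL) {
  if (any(grid_mu < 0 | grid_mu > 1) || any(grid_sigma < 0 | grid_sigma >= 1)) {
    abort_bad("grid values must lie in [0, 1] (uc_sigma strictly below 1).")
  }
  static <- replay_static(offline, online, regularization = regularization,
                          tick = tick, timeout = timeout)
  cells <- tidyr::crossing(uc_mu = sort(grid_mu), uc_sigma = sort(grid_sigma))
  res <- purrr::pmap(cells, function(uc_mu, uc_sigma) {
    r <- replay_adaptive(offline, online, uc_pair(uc_mu, uc_sigma),
                         regularization = regularization,
                         update_mode = update_mode,
                         tick = tick, timeout = timeout)
    tibble::tibble(adaptive_pa = r$pa, adaptive_bias = r$bias)
  })
  out <- dplyr::bind_cols(cells, dplyr::bind_rows(res))
  out <- dplyr::mutate(
    out,
    modulated_pa = .data$adaptive_pa - static$pa,
    modulated_bias = .data$adaptive_bias - static$bias
  )
  attr(out, "static_pa") <- static$pa
  attr(out, "static_bias") <- static$bias
  attr(out, "dataset_id") <- dataset_id
  class(out) <- c("sim_matrices", class(out))
  out
}

check_same_grid <- function(sims) {
  ref <- sims[[1]][, c("uc_mu", "uc_sigma")]
  for (s in sims[-1]) {
    if (nrow(s) != nrow(ref) ||
        !isTRUE(all.equal(as.data.frame(s[, c("uc_mu", "uc_sigma")]),
                          as.data.frame(ref), check.attributes = FALSE))) {
      abort_bad("all simulation matrices must share the same UC grid.")
    }
  }
  invisible(ref)
}

#' Aggregate simulation matrices across datasets
#'
#' Computes, per UC pair, the elementwise mean modulated PA, the consistency
#' score (number of datasets with strictly positive modulated PA; null or
#' negative values score 0) and the mean modulated bias.
#'
#' @param sims A list of `sim_matrices` from [grid_search()], all on the same
#'   grid.
#' @return A tibble of class `uc_summary` with columns `uc_mu`, `uc_sigma`,
#'   `mean_modulated_pa`, `consistency`, `mean_modulated_bias`; the number of
#'   datasets is attached as attribute `n_datasets`.
#' @export
aggregate_sim <- function(sims) {
  if (inherits(sims, "sim_matrices")) sims <- list(sims)
  if (length(sims) < 1L) abort_bad("need at least one simulation matrix.")
  purrr::walk(sims, function(s) stopifnot(inherits(s, "sim_matrices")))
  check_same_grid(sims)
  stacked <- dplyr::bind_rows(lapply(sims, tibble::as_tibble))
  out <- dplyr::summarise(
    dplyr::group_by(stacked, .data$uc_mu, .data$uc_sigma),
    mean_modulated_pa = mean(.data$modulated_pa),
    consistency = sum(.data$modulated_pa > 0),
    mean_modulated_bias = mean(.data$modulated_bias),
    .groups = "drop"
  )
  attr(out, "n_datasets") <- length(sims)
  class(out) <- c("uc_summary", class(out))
  out
}

#' Select the group-level update-coefficient pair
#'
#' Tri-criterion policy: restrict to UC pairs whose mean modulated PA lies
#' within `pa_tolerance` percentage points of the maximum, then keep the pairs
#' with the highest consistency score, then the lowest mean modulated bias;
#' remaining ties break toward the smallest `uc_mu`, then smallest `uc_sigma`
#' (slower adaptation is the safer default). The full candidate ranking is
#' attached for audit.
#'
#' @param summary A `uc_summary` from [aggregate_sim()].
#' @param pa_tolerance Width of the near-maximum band on mean modulated PA, in
#'   percentage points (default 0.5).
#' @return A one-row tibble with the selected `uc_mu`, `uc_sigma` and their
#'   three criterion values; the ranked candidate table is attached as
#'   attribute `ranking`.
#' @export
select_uc_pair <- function(summary, pa_tolerance = 0.5) {
  stopifnot(inherits(summary, "uc_summary"))
  if (nrow(summary) == 0L) abort_bad("empty summary.")
  if (!is_number(pa_tolerance) || pa_tolerance < 0) {
    abort_bad("`pa_tolerance` must be >= 0.")
  }
  ranked <- dplyr::arrange(
    tibble::as_tibble(summary),
    dplyr::desc(.data$mean_modulated_pa >= max(.data$mean_modulated_pa) - pa_tolerance),
    dplyr::desc(.data$consistency),
    .data$mean_modulated_bias,
    .data$uc_mu,
    .data$uc_sigma
  )
  out <- ranked[1, ]
  attr(out, "ranking") <- ranked
  out
}

#' Per-dataset update-coefficient selection
#'
#' Selects, for each dataset independently, the UC pair with the largest
#' modulated PA (ties broken toward the smallest `uc_mu`, then the smallest
#' `uc_sigma`). By construction the selected pair's adaptive PA on the
#' selection data dominates any fixed pair, including a group-level choice.
#'
#' @param sims A list of `sim_matrices` (or a single one).
#' @return A tibble with one row per dataset: `dataset_id`, `uc_mu`,
#'   `uc_sigma`, `modulated_pa`, `adaptive_pa`.
#' @export
select_individual_uc <- function(sims) {
  if (inherits(sims, "sim_matrices")) sims <- list(sims)
  if (length(sims) < 1L) abort_bad("need at least one simulation matrix.")
  rows <- purrr::imap(sims, function(s, i) {
    stopifnot(inherits(s, "sim_matrices"))
    best <- dplyr::arrange(
      tibble::as_tibble(s),
      dplyr::desc(.data$modulated_pa), .data$uc_mu, .data$uc_sigma
    )[1, ]
    tibble::tibble(
      dataset_id = attr(s, "dataset_id") %||% as.character(i),
      uc_mu = best$uc_mu, uc_sigma = best$uc_sigma,
      modulated_pa = best$modulated_pa,
      adaptive_pa = best$adaptive_pa
    )
  })
  dplyr::bind_rows(rows)
}
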