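heatmap_base <- function(df, fill, title, fill_lab) {
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$uc_sigma), y = factor(.data$uc_mu),
    fill = {{ fill }}
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#3b4cc0", mid = "white",
                                  high = "#b40426", midpoint = 0) +
    ggplot2::labs(
      x = expression(UC[Sigma]), y = expression(UC[mu]),
      fill = fill_lab, title = title
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Heatmaps of a single-dataset UC grid search
#'
#' @param object A `sim_matrices` tibble from [grid_search()].
#' @param metric Which matrix to draw: `"modulated_pa"` (default),
#'   `"adaptive_pa"` or `"modulated_bias"`.
#' @param ... Unused.
#' @return A ggplot with `uc_sigma` on the x axis and `uc_mu` on the y axis.
#' @export
autoplot.sim_matrices <- function(object,
                                  metric = c("modulated_pa", "adaptive_pa",
                                             "modulated_bias"),
                                  ...) {
  metric <- match.arg(metric)
  titles <- c(
    modulated_pa = "Modulated PA (adaptive - static, % points)",
    adaptive_pa = "Adaptive PA (%)",
    modulated_bias = "Modulated bias (adaptive - static, % points)"
  )
  heatmap_base(tibble::as_tibble(object), .data[[metric]],
               titles[[metric]], metric)
}

#' Heatmaps of aggregated UC selection matrices
#'
#' Draws the three selection matrices (mean modulated PA, consistency score,
#' mean modulated bias) side by side, in the conventional orientation
#' (`uc_sigma` on x, `uc_mu` on y).
#'
#' @param object A `uc_summary` from [aggregate_sim()].
#' @param ... Unused.
#' @return A ggplot (faceted over the three metrics).
#' @export
autoplot.uc_summary <- function(object, ...) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    cols = c("mean_modulated_pa", "consistency", "mean_modulated_bias"),
    names_to = "metric", values_to = "value"
  )
  df$metric <- factor(df$metric, levels = c(
    "mean_modulated_pa", "consistency", "mean_modulated_bias"
  ))
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$uc_sigma), y = factor(.data$uc_mu), fill = .data$value
  )) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = expression(UC[Sigma]), y = expression(UC[mu])) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Per-trial probability trajectory of a replay
#'
#' Plots the window-averaged cued-class probability of every replayed trial in
#' acquisition order; the dashed line marks the 0.5 decision threshold.
#'
#' @param object A `replay_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.replay_result <- function(object, ...) {
  df <- object$per_trial
  ggplot2::ggplot(df, ggplot2::aes(
    x = seq_len(nrow(df)), y = .data$mean_probability,
    colour = factor(.data$cued_class), shape = .data$correct
  )) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line(ggplot2::aes(group = 1), alpha = 0.3, colour = "grey50") +
    ggplot2::labs(
      x = "online trial", y = "mean cued-class probability",
      colour = "cued class", shape = "correct",
      title = sprintf("%s replay: PA = %.1f%%, bias = %.1f",
                      object$classifier_mode, object$pa, object$bias)
    ) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
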