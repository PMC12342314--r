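#' Plot a spike-density function
#'
#' @param object An [compute_sdf()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sdf <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time_ms, .data$density)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::labs(x = "Time from tone onset (ms)", y = "Firing rate (spikes/s)",
                  title = sprintf("Spike-density function (%d trials, kernel SD %g ms)",
                                  attr(object, "n_trials"), attr(object, "kernel_sd"))) +
    ggplot2::theme_minimal()
}

#' Plot a frequency response area
#'
#' Heatmap of response magnitude over frequency x level; excitatory cells
#' are outlined.
#'
#' @param object An [build_fra()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fra <- function(object, ...) {
  g <- object$grid
  ggplot2::ggplot(g, ggplot2::aes(factor(round(.data$frequency_hz)),
                                  factor(.data$level_db))) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$response)) +
    ggplot2::geom_tile(data = g[g$excitatory, , drop = FALSE],
                       fill = NA, colour = "black", linewidth = 0.4) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "Frequency (Hz)", y = "Level (dB SPL)",
                  fill = "Response\n(spikes)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a power-law adaptation fit
#'
#' @param object A [fit_power_law()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.power_law_fit <- function(object, ...) {
  d <- object$data
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$trial, .data$mean_response)) +
    ggplot2::geom_point(colour = "grey30", size = 1.2) +
    ggplot2::labs(x = "Trial", y = "Mean response (spikes)") +
    ggplot2::theme_minimal()
  if (object$converged) {
    d$fitted <- object$fitted
    p <- p + ggplot2::geom_line(data = d, ggplot2::aes(y = .data$fitted),
                                colour = "#d95f02", linewidth = 0.8) +
      ggplot2::labs(subtitle = sprintf("y = %.3g t^%.3g + %.3g  (r² = %.2f)",
                                       object$a, object$b, object$c, object$r2))
  }
  p
}

#' Plot adaptation time courses by condition
#'
#' @param trial_responses Tibble with `condition`, `trial`, `response` and
#'   `unit_id` columns (e.g. the `trial_responses` element of a pipeline
#'   run, possibly pre-filtered to one stratum).
#' @return A ggplot object.
#' @export
plot_time_course <- function(trial_responses) {
  d <- trial_responses |>
    group_by(.data$condition, .data$trial) |>
    summarise(mean_response = mean(.data$response),
              se = sd(.data$response) / sqrt(n()), .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(.data$trial, .data$mean_response,
                                  colour = .data$condition,
                                  fill = .data$condition)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_response - .data$se,
                                      ymax = .data$mean_response + .data$se),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = c(DEV = "#d7191c", STD = "#2c7bb6",
                                            CAS = "#1a9641"),
                                 aesthetics = c("colour", "fill")) +
    ggplot2::labs(x = "Analysed trial", y = "Baseline-corrected spikes",
                  colour = "Condition", fill = "Condition") +
    ggplot2::theme_minimal()
}

#' Plot per-point mismatch indices by group
#'
#' @param points An [index_table()] result.
#' @param measure Index column to plot (default `"imm"`).
#' @return A ggplot object.
#' @export
plot_indices <- function(points, measure = "imm") {
  points$group <- paste(points$sex, points$age, points$exposure, sep = "\n")
  ggplot2::ggplot(points, ggplot2::aes(.data$group, .data[[measure]],
                                       fill = .data$exposure)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_grid(division ~ level_class) +
    ggplot2::labs(x = NULL, y = toupper(measure)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
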