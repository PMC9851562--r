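#' Mean time-normalized trajectories per condition
#'
#' Averages the aligned, time-normalized trajectories pointwise within each
#' condition and draws them in aligned coordinates, with the direct path as
#' reference.
#'
#' @param tnorm Output of [time_normalize()].
#' @param trials Trial metadata supplying `condition`.
#' @return A ggplot object.
#' @export
plot_mean_trajectories <- function(tnorm, trials) {
  d <- tnorm |>
    dplyr::left_join(
      dplyr::select(trials, "participant_id", "trial_index", "condition"),
      by = c("participant_id", "trial_index")
    ) |>
    dplyr::group_by(.data$condition, .data$step) |>
    dplyr::summarise(x = mean(.data$x), y = mean(.data$y), .groups = "drop") |>
    dplyr::mutate(condition = condition_factor(.data$condition))
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y, colour = .data$condition)) +
    ggplot2::annotate("segment", x = 0, y = 0, xend = 1, yend = 1.5,
                      linetype = "dotted", colour = "grey40") +
    ggplot2::geom_path(linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (aligned units)", y = "y (aligned units)",
                  colour = "Stimulus type",
                  title = "Mean time-normalized trajectories") +
    ggplot2::theme_minimal()
}

#' Component estimates with confidence intervals
#'
#' Point-and-interval display of the eight Stroop components of one measure.
#'
#' @param object A `stroop_components` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot stroop_components
#' @export
autoplot.stroop_components <- function(object, ...) {
  d <- dplyr::mutate(object,
                     component = factor(.data$component,
                                        levels = rev(component_table()$component)))
  ggplot2::ggplot(d, ggplot2::aes(.data$estimate, .data$component)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high)) +
    ggplot2::labs(
      x = paste0("Estimate (", attr(object, "measure") %||% "measure", ", ",
                 100 * object$ci_level[1], "% CI)"),
      y = NULL, title = "Stroop component decomposition"
    ) +
    ggplot2::theme_minimal()
}

#' Component time courses across normalized time
#'
#' Draws per-step component estimates with confidence ribbons and marks the
#' sustained-significance intervals along the top.
#'
#' @param object A `stroop_timecourse`.
#' @param components Components to show (default the total effect and its two
#'   first-level constituents).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot stroop_timecourse
#' @export
autoplot.stroop_timecourse <- function(object,
                                       components = c("total_stroop",
                                                      "interference",
                                                      "facilitation"),
                                       ...) {
  d <- dplyr::filter(object$steps, .data$component %in% components)
  iv <- dplyr::filter(object$intervals, .data$component %in% components)
  ytop <- max(d$ci_high, na.rm = TRUE) * 1.05
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$step, .data$estimate,
                                       colour = .data$component,
                                       fill = .data$component)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Normalized time step",
                  y = paste0(object$measure, " contrast (",
                             100 * object$ci_level, "% CI)"),
                  title = "Stroop components across normalized movement time") +
    ggplot2::theme_minimal()
  if (nrow(iv) > 0) {
    p <- p + ggplot2::geom_segment(
      data = iv,
      ggplot2::aes(x = .data$start_step, xend = .data$end_step,
                   y = ytop, yend = ytop, colour = .data$component),
      inherit.aes = FALSE, linewidth = 1.5
    )
  }
  if (object$measure == "x_coordinate") p <- p + ggplot2::scale_y_reverse()
  p
}

#' Cluster mean paths
#'
#' One panel per cluster showing its pointwise mean space-normalized
#' trajectory; partial-error clusters are flagged in the panel label.
#'
#' @param object A `stroop_clusters`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot stroop_clusters
#' @export
autoplot.stroop_clusters <- function(object, ...) {
  d <- object$mean_paths |>
    dplyr::mutate(label = ifelse(.data$cluster %in% object$pe_clusters,
                                 paste0("Cl", .data$cluster, " (PE)"),
                                 paste0("Cl", .data$cluster)))
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::annotate("segment", x = 0, y = 0, xend = 1, yend = 1.5,
                      linetype = "dotted", colour = "grey40") +
    ggplot2::geom_path(colour = "darkgreen", linewidth = 0.8) +
    ggplot2::facet_wrap(~label) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (aligned units)", y = "y (aligned units)",
                  title = "Cluster mean trajectories") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
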