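#' Plot a cumulative interval trajectory
#'
#' Line-and-ribbon chart of a `ref_trajectory`: the observation series, the
#' evolving interval bounds, and flags coloured by outcome; faceted by method
#' (and subject, if several are present).
#'
#' @param object a `ref_trajectory` tibble from [cumulative_trajectory()] or
#'   [panel_trajectories()].
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot ref_trajectory
#' @export
autoplot.ref_trajectory <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$k)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "steelblue", alpha = 0.2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$center), colour = "steelblue",
                       linetype = 2, na.rm = TRUE) +
    ggplot2::geom_line(ggplot2::aes(y = .data$observation), colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(y = .data$observation, colour = .data$flag),
                        size = 2) +
    ggplot2::scale_colour_manual(values = c(within = "forestgreen",
                                            below = "firebrick",
                                            above = "firebrick",
                                            not_evaluable = "grey60")) +
    ggplot2::facet_grid(subject_id ~ method) +
    ggplot2::labs(x = "visit", y = "value", colour = "flag") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.ref_trajectory
#' @param trajectory a `ref_trajectory` tibble.
#' @export
plot_trajectory <- function(trajectory, ...) {
  autoplot.ref_trajectory(trajectory, ...)
}

#' Plot inter- vs intra-individual coefficients of variation
#'
#' Bar chart of each subject's CV across their own visits, with horizontal
#' lines for the panel CV(inter) and the mean CV(intra) — the visual argument
#' that individuals vary far less within themselves than the population does
#' across people.
#'
#' @param panel a panel tibble.
#' @return A ggplot object.
#' @export
plot_cv_comparison <- function(panel) {
  subj <- subject_summaries(panel)
  summ <- panel_summary(panel)
  ggplot2::ggplot(subj, ggplot2::aes(x = .data$subject_id, y = .data$cv_percent)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_hline(yintercept = summ$cv_inter_percent, colour = "firebrick",
                        linetype = 1) +
    ggplot2::geom_hline(yintercept = summ$mean_cv_intra_percent,
                        colour = "steelblue", linetype = 2) +
    ggplot2::labs(
      x = "subject", y = "CV (%)",
      title = sprintf("%s: CV(inter) %.1f%% (red) vs mean CV(intra) %.1f%% (blue)",
                      panel$analyte[1], summ$cv_inter_percent,
                      summ$mean_cv_intra_percent)
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Plot per-subject intervals by method
#'
#' Range plot of every subject's personal interval for each method, with the
#' population range shaded behind.
#'
#' @param intervals tibble from [panel_intervals()].
#' @param population optional one-row population interval tibble
#'   ([population_range()]) drawn as a shaded band.
#' @return A ggplot object.
#' @export
plot_intervals <- function(intervals, population = NULL) {
  p <- ggplot2::ggplot(intervals,
                       ggplot2::aes(x = .data$subject_id, y = .data$center))
  if (!is.null(population)) {
    p <- p + ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                               ymin = population$lower, ymax = population$upper,
                               fill = "grey85", alpha = 0.6)
  }
  p +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                             size = 0.3) +
    ggplot2::facet_wrap(~method) +
    ggplot2::labs(x = "subject", y = "value") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
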