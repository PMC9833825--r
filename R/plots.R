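#' YFP vs CFP fraction scatter of population fluorescence
#'
#' The classic two-channel view: normalized bulk YFP against normalized CFP,
#' one point per population (optionally per day), coloured by fraction label,
#' with the threshold boundaries and the amplification diagonal drawn.
#'
#' @param fluor Output of [population_fluorescence()] (columns `yfp_norm`,
#'   `cfp_norm`, optionally `day`).
#' @param t [thresholds()].
#' @return A ggplot object.
#' @export
plot_fraction_scatter <- function(fluor, t = thresholds()) {
  d <- classify_population(fluor, t)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$cfp_norm, y = .data$yfp_norm,
                                       colour = .data$label)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey60") +
    ggplot2::geom_vline(xintercept = t$theta_c, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_hline(yintercept = t$theta_y, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "normalized CFP (copy-number proxy)",
                  y = "normalized YFP (expression proxy)",
                  colour = "fraction") +
    ggplot2::theme_minimal()
  if ("day" %in% names(d)) p <- p + ggplot2::aes(alpha = .data$day)
  p
}

#' Single-cell event scatter
#'
#' @param events Raw or classified event tibble (`yfp`, `cfp`, optionally
#'   `label`).
#' @return A ggplot object.
#' @export
plot_flow_events <- function(events) {
  aes <- if ("label" %in% names(events)) {
    ggplot2::aes(x = .data$cfp, y = .data$yfp, colour = .data$label)
  } else {
    ggplot2::aes(x = .data$cfp, y = .data$yfp)
  }
  ggplot2::ggplot(events, aes) +
    ggplot2::geom_point(size = 0.4, alpha = 0.4) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "CFP", y = "YFP") +
    ggplot2::theme_minimal()
}

#' Class-frequency trajectories of a simulated experiment
#'
#' Stacked per-day frequencies of the biologically distinct classes:
#' ancestral, amplified-only (k >= 2, m = 0), point-mutant-only (k = 1,
#' m = 1), combination (k >= 2, m >= 1), faceted by replicate.
#'
#' @param object A `dupdiv_experiment`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.dupdiv_experiment <- function(object, ...) {
  d <- class_frequencies(object) |>
    dplyr::mutate(class = dplyr::case_when(
      .data$k == 1 & .data$m == 0 ~ "ancestral",
      .data$k >= 2 & .data$m == 0 ~ "amplified",
      .data$k == 1 & .data$m == 1 ~ "point mutant",
      TRUE ~ "combination"
    )) |>
    dplyr::group_by(.data$replicate, .data$day, .data$class) |>
    dplyr::summarise(frequency = sum(.data$frequency), .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$day, y = .data$frequency,
                                  fill = .data$class)) +
    ggplot2::geom_area() +
    ggplot2::facet_wrap(~replicate) +
    ggplot2::labs(x = "day", y = "class frequency") +
    ggplot2::theme_minimal()
}
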