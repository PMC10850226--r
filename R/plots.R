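#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Forest plot of the mediation odds ratios
#'
#' Total, natural direct and natural indirect effects on a log odds-ratio
#' axis, with the proportion mediated annotated in the subtitle.
#'
#' @param object An `fi_mediation` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fi_mediation
#' @export
autoplot.fi_mediation <- function(object, ...) {
  est <- dplyr::mutate(
    object$estimates,
    term = factor(.data$term,
                  levels = rev(c("total_effect", "natural_direct",
                                 "natural_indirect")),
                  labels = rev(c("Total effect", "Natural direct",
                                 "Natural indirect")))
  )
  ggplot2::ggplot(est, ggplot2::aes(x = .data$or, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_lo,
                                          xmax = .data$ci_hi)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = sprintf("Odds ratio per %.3g-year age increment",
                  object$spec$a - object$spec$a_star),
      y = NULL,
      title = sprintf("Age effect on %s mediated by frailty",
                      object$outcome),
      subtitle = sprintf("Proportion mediated %.1f%% (%.1f%%-%.1f%%)",
                         100 * object$pm$pm, 100 * object$pm$ci_lo,
                         100 * object$pm$ci_hi)
    ) +
    ggplot2::theme_minimal()
}

#' Histogram of the frailty-index distribution
#'
#' @param data Cohort tibble with an `fi` column.
#' @param binwidth Histogram bin width (default 0.025).
#' @return A ggplot.
#' @export
plot_fi_distribution <- function(data, binwidth = 0.025) {
  stopifnot("fi" %in% names(data))
  d <- fi_distribution(data)
  ggplot2::ggplot(data[!is.na(data$fi), ],
                  ggplot2::aes(x = .data$fi)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = d$median, linetype = "dashed") +
    ggplot2::labs(
      x = "Frailty index (deficits present / deficits assessed)",
      y = "Participants",
      title = sprintf("Frailty index: median %.2f (Q1 %.2f, Q3 %.2f)",
                      d$median, d$q1, d$q3)
    ) +
    ggplot2::theme_minimal()
}
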