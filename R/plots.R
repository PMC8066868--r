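# Quick-look figures for the emitted result tables.

#' Cost-effectiveness plane of PSA draws
#'
#' @param psa A `psa_result`.
#' @param wtp Optional willingness-to-pay threshold drawn as a line.
#' @return A ggplot object.
#' @export
plot_ce_plane <- function(psa, wtp = NULL) {
  draws <- psa$draws
  p <- ggplot2::ggplot(draws,
                       ggplot2::aes(x = .data$delta_qaly,
                                    y = .data$delta_cost)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.6, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost (SGD)",
                  title = "Cost-effectiveness plane")
  if (!is.null(wtp))
    p <- p + ggplot2::geom_abline(slope = wtp, intercept = 0,
                                  colour = "grey40")
  p
}

#' @export
autoplot.psa_result <- function(object, ...) plot_ce_plane(object, ...)

#' Cost-effectiveness acceptability curve
#'
#' @param x A `ceac` tibble from [ceac()].
#' @return A ggplot object.
#' @export
plot_ceac <- function(x) {
  ggplot2::ggplot(x, ggplot2::aes(x = .data$wtp, y = .data$probability)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay (SGD/QALY)",
                  y = "P(cost-effective)",
                  title = "Cost-effectiveness acceptability curve")
}

#' @export
autoplot.ceac <- function(object, ...) plot_ceac(object)

#' Tornado diagram of the one-way sensitivity analysis
#'
#' @param x A `tornado` tibble from [run_osa()].
#' @param top Number of parameters shown (widest spans first).
#' @return A ggplot object.
#' @export
plot_tornado <- function(x, top = 12) {
  d <- utils::head(x, top)
  d$parameter <- factor(d$parameter, levels = rev(d$parameter))
  ggplot2::ggplot(d, ggplot2::aes(y = .data$parameter)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$icer_at_low,
                                       xend = .data$icer_at_high,
                                       yend = .data$parameter),
                          linewidth = 4, colour = "steelblue") +
    ggplot2::labs(x = "ICER (SGD/QALY)", y = NULL,
                  title = "One-way sensitivity of the ICER")
}

#' @export
autoplot.tornado <- function(object, ...) plot_tornado(object, ...)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
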