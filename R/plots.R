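#' Plot raw luminescence traces
#'
#' @param traces Long trace tibble (or `lucifit_study`).
#' @return A ggplot: intensity vs time, coloured by nominal S0, faceted by
#'   series when present.
#' @export
plot_traces <- function(traces) {
  if (inherits(traces, "lucifit_study")) traces <- traces$traces
  p <- ggplot2::ggplot(traces,
                       ggplot2::aes(x = .data$time_s, y = .data$intensity_rlu,
                                    colour = factor(.data$S0_uM),
                                    group = .data$well)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::labs(x = "time (s)", y = "intensity (RLU)", colour = "S0 (uM)")
  if (all(c("variant", "luciferin") %in% names(traces))) {
    p <- p + ggplot2::facet_wrap(~ variant + luciferin, scales = "free")
  }
  p
}

#' Fitted conversion curves against the data
#'
#' @param object A `lucifit_fit`.
#' @param ... Unused.
#' @return A ggplot of observed (points) and fitted (lines) cumulative
#'   luminescence per concentration level.
#' @export
autoplot.lucifit_fit <- function(object, ...) {
  aug <- augment(object)
  ggplot2::ggplot(aug, ggplot2::aes(x = .data$time_s, group = .data$well)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$cumulative_rlu_s,
                                     colour = factor(.data$S0_uM)),
                        size = 0.4, alpha = 0.5) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), linewidth = 0.3) +
    ggplot2::labs(x = "time after injection (s)", y = "cumulative luminescence (RLU.s)",
                  colour = "S0 (uM)")
}

#' Confidence-contour map
#'
#' @param object A `lucifit_contours`.
#' @param ... Unused.
#' @return A ggplot of the profiled chi-squared surface with the confidence
#'   boundary and the best-fit point.
#' @export
autoplot.lucifit_contours <- function(object, ...) {
  g <- object$grid
  ggplot2::ggplot(g, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = log10(.data$chi2))) +
    ggplot2::geom_contour(ggplot2::aes(z = .data$chi2),
                          breaks = object$threshold, colour = "white") +
    ggplot2::annotate("point", x = object$estimate[1], y = object$estimate[2],
                      colour = "red", shape = 3) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = object$pair[1], y = object$pair[2],
                  fill = "log10 chi2")
}
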