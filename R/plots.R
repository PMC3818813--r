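#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an activation map
#'
#' Heatmap of the auditory layer's activity (azimuth x frequency) at the
#' state's time point, with the visual layer's activity profile available
#' through [tidy.ventnet_state()].
#'
#' @param object a `ventnet_state`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.ventnet_state <- function(object, ...) {
  df <- dplyr::filter(tidy(object), .data$layer == "auditory")
  ggplot2::ggplot(df, ggplot2::aes(.data$azimuth_deg, .data$freq_index,
                                   fill = .data$activity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "azimuth (deg)", y = "frequency index",
                  fill = "activity",
                  title = sprintf("auditory activity at t = %g ms", object$t)) +
    ggplot2::theme_minimal()
}

#' Plot tuning curves
#'
#' Line plot of a [azimuth_tuning()] or [frequency_tuning()] result, one
#' line per probe intensity.
#'
#' @param object a `ventnet_tuning` tibble.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.ventnet_tuning <- function(object, ...) {
  axis <- attr(object, "axis")
  lab <- if (axis == "probe_azimuth_deg") "probe azimuth (deg)"
         else "probe frequency index"
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data[[axis]], .data$response,
                               colour = factor(.data$intensity))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = lab, y = "steady-state response",
                  colour = expression(E[0]^a)) +
    ggplot2::theme_minimal()
}

#' Plot a frequency response area
#'
#' Banded frequency x intensity map of a neuron's normalized response, in
#' the four conventional bands (<25%, 25-50%, 50-75%, >75% of peak).
#'
#' @param object a `ventnet_fra` tibble from [fra()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.ventnet_fra <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$probe_freq_index, .data$intensity,
                               fill = .data$band)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_d(drop = FALSE) +
    ggplot2::labs(x = "probe frequency index", y = "intensity",
                  fill = "response") +
    ggplot2::theme_minimal()
}

#' Plot a ventriloquism sweep
#'
#' Auditory perceptual shift as a function of visual-auditory disparity,
#' one line per tone intensity.
#'
#' @param object a `ventnet_sweep` tibble from [ventriloquism_sweep()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.ventnet_sweep <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$disparity, .data$shift_auditory,
                               colour = factor(.data$intensity))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "visual-auditory disparity (deg)",
                  y = "auditory shift (deg)",
                  colour = expression(E[0]^a)) +
    ggplot2::theme_minimal()
}

#' Plot aftereffect generalization curves
#'
#' Aftereffect (degrees) versus octave distance from the adaptation
#' frequency, faceted by adaptation intensity with one line per test
#' intensity.
#'
#' @param object a `ventnet_aftereffect` tibble.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.ventnet_aftereffect <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$octaves_from_adapt, .data$shift_deg,
                               colour = factor(.data$test_intensity))) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$adapt_intensity),
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "octaves from adaptation frequency",
                  y = "aftereffect (deg)", colour = "test intensity") +
    ggplot2::theme_minimal()
}
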