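#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an attention-marker series
#'
#' @param object An `aad_markers` tibble.
#' @param ... Unused.
#' @return A ggplot: the two marker streams over time.
#' @export
autoplot.aad_markers <- function(object, ...) {
  d <- tidyr::pivot_longer(tibble::as_tibble(object), c("m1", "m2"),
                           names_to = "speaker", values_to = "marker")
  d$speaker <- ifelse(d$speaker == "m1", "speaker 1", "speaker 2")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t_s, y = .data$marker,
                                  colour = .data$speaker)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)",
                  y = sprintf("%s marker", attr(object, "marker_type")),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an attentional-state trajectory
#'
#' Probability of attending to speaker 1 with its 90% confidence ribbon.
#'
#' @param object An `aad_trajectory` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.aad_trajectory <- function(object, ...) {
  d <- tibble::as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t_s, y = .data$p)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_lo,
                                      ymax = .data$ci_hi),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (s)", y = "P(attending speaker 1)",
                  subtitle = sprintf("%s estimator", attr(object, "mode"))) +
    ggplot2::theme_minimal()
}

#' Plot estimated lag-domain coefficients over time
#'
#' Heat map of the decoder/TRF estimates per window for one speaker.
#'
#' @param stream An `aad_coef_stream`.
#' @param speaker 1 or 2.
#' @return A ggplot.
#' @export
plot_coefficients <- function(stream, speaker = 1L) {
  d <- dplyr::filter(tidy(stream), .data$speaker == !!speaker,
                     !is.na(.data$lag_s))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t_s, y = .data$lag_s,
                                  fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::labs(x = "time (s)", y = "lag (s)",
                  fill = "coefficient") +
    ggplot2::theme_minimal()
}

#' Plot a forward-lag sweep
#'
#' Mean probability-scale MSE against the batch benchmark, as a function
#' of the forward lag.
#'
#' @param sweep A tibble from [sweep_forward_lag()].
#' @return A ggplot.
#' @export
plot_forward_lag_sweep <- function(sweep) {
  ggplot2::ggplot(sweep, ggplot2::aes(x = .data$K_F_s,
                                      y = .data$mean_mse)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "forward lag (s)", y = "mean MSE vs batch") +
    ggplot2::theme_minimal()
}
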