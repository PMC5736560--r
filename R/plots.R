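#' Plot percentile curves on a semi-log scale
#'
#' Solid line: 50th percentile; dotted lines: outer percentiles.
#' Concentration is drawn on a log10 axis, age on a linear axis.
#'
#' @param object A [percentile_curves()] result.
#' @param observations Optional tibble with `age` and `value` columns to
#'   overlay as points.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.centile_curves <- function(object, observations = NULL, ...) {
  df <- dplyr::mutate(tibble::as_tibble(object),
                      role = ifelse(.data$level == 50, "median", "outer"))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$age, .data$value,
                                        group = .data$level)) +
    ggplot2::geom_line(ggplot2::aes(linetype = .data$role)) +
    ggplot2::scale_linetype_manual(
      values = c(median = "solid", outer = "dotted"), guide = "none") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Age (years)", y = "Concentration (pg/mL)",
                  subtitle = paste0("5th/50th/95th percentile (",
                                    attr(object, "basis"), " basis)")) +
    ggplot2::theme_minimal()
  if (!is.null(observations)) {
    p <- p + ggplot2::geom_point(
      data = observations,
      ggplot2::aes(.data$age, .data$value),
      inherit.aes = FALSE, alpha = 0.3, size = 0.8)
  }
  p
}

#' @rdname autoplot.centile_curves
#' @param curves A [percentile_curves()] result.
#' @export
plot_centiles <- function(curves, observations = NULL) {
  autoplot.centile_curves(curves, observations)
}

#' Plot a visual predictive check
#'
#' Observed binned percentiles (points and lines) over the 90% simulated
#' prediction band of each percentile (ribbons), on a semi-log scale.
#'
#' @param object A [vpc()] result.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.vpc_result <- function(object, ...) {
  df <- object$bins
  ggplot2::ggplot(df, ggplot2::aes(.data$age_mid,
                                   group = factor(.data$level))) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$band_lo,
                                      ymax = .data$band_hi),
                         alpha = 0.2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$observed,
                                    linetype = factor(.data$level))) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed)) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Age (years)", y = "Concentration (pg/mL)",
                  linetype = "Percentile",
                  subtitle = sprintf(
                    "Observed percentiles vs 90%% bands (%d replicates)",
                    object$n_replicates)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.vpc_result
#' @param x A [vpc()] result.
#' @export
plot_vpc <- function(x) autoplot.vpc_result(x)
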