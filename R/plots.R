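#' Plot a calibration model
#'
#' Calibrant responses with the fitted line over the model's segment, on
#' log-shifted axes so the four-decade ladder stays readable.
#'
#' @param object An `mfs_calibration`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mfs_calibration
#' @export
autoplot.mfs_calibration <- function(object, ...) {
  dat <- object$data
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$conc, y = .data$response)) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::labs(
      title = paste0(object$analyte_id, " matrix-fortified calibration"),
      subtitle = sprintf("segment %g-%g ng/kg, %s weights",
                         object$segment[1], object$segment[2],
                         object$weighting),
      x = "fortification level (ng/kg)",
      y = "blank-corrected response ratio"
    )
}

#' Plot validation summaries
#'
#' Apparent recovery per analyte and spike level with the acceptance band,
#' coloured by the quantitative/qualitative verdict when present.
#'
#' @param object Validation summary tibble from [aggregate_validation()]
#'   (optionally joined with verdicts, as `run_pipeline()` emits).
#' @param criteria Recovery acceptance band, default c(65, 135).
#' @return A ggplot object.
#' @export
plot_validation <- function(object, criteria = c(65, 135)) {
  p <- ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$analyte_id, y = .data$recovery_mean)
  ) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                      ymin = criteria[1], ymax = criteria[2],
                      alpha = 0.12, fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 100, linetype = 2, colour = "grey50")
  if ("verdict" %in% names(object)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$verdict,
                                              shape = factor(.data$spike_level)))
  } else {
    p <- p + ggplot2::geom_point(ggplot2::aes(shape = factor(.data$spike_level)))
  }
  p +
    ggplot2::labs(x = NULL, y = "apparent recovery (%)",
                  shape = "spike (ng/kg)") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Plot an MRM trace with its integration result
#'
#' @param trace Tibble (time_min, intensity) for one transition.
#' @param peak Optional one-row result of [process_trace()] to annotate the
#'   apex.
#' @return A ggplot object.
#' @export
plot_trace <- function(trace, peak = NULL) {
  p <- ggplot2::ggplot(trace, ggplot2::aes(x = .data$time_min,
                                           y = .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "retention time (min)", y = "intensity")
  if (!is.null(peak) && isTRUE(peak$found)) {
    p <- p + ggplot2::geom_vline(xintercept = peak$rt_apex,
                                 linetype = 3, colour = "red")
  }
  p
}
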