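#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a calibration model
#'
#' @param x An `mfs_calibration`.
#' @param ... Unused.
#' @return Tibble with one row per model term (intercept, slope).
#' @method tidy mfs_calibration
#' @export
tidy.mfs_calibration <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", "conc"),
    estimate = c(x$intercept, x$slope)
  )
}

#' One-row summary of a calibration model
#'
#' @param x An `mfs_calibration`.
#' @param ... Unused.
#' @return Tibble with analyte, segment bounds, fit and reference values.
#' @method glance mfs_calibration
#' @export
glance.mfs_calibration <- function(x, ...) {
  tibble::tibble(
    analyte_id = x$analyte_id,
    slope = x$slope,
    intercept = x$intercept,
    segment_low = x$segment[1],
    segment_high = x$segment[2],
    weighting = x$weighting,
    r_squared = x$r_squared,
    ref_ion_ratio = x$ref_ion_ratio,
    ref_rrt = x$ref_rrt,
    n_points = x$n_points
  )
}

#' Tidy a stability ANOVA result
#'
#' @param x A `stability_result`.
#' @param ... Unused.
#' @return Tibble with one row per group (label, n, mean).
#' @method tidy stability_result
#' @export
tidy.stability_result <- function(x, ...) {
  x$group_rsds |>
    dplyr::summarise(
      n = dplyr::n(), mean = mean(.data$value), sd = stats::sd(.data$value),
      .by = "group"
    )
}

#' One-row summary of a stability ANOVA
#'
#' @param x A `stability_result`.
#' @param ... Unused.
#' @return Tibble with the F statistic, degrees of freedom and p value.
#' @method glance stability_result
#' @export
glance.stability_result <- function(x, ...) {
  tibble::tibble(
    f_statistic = x$f_statistic,
    df_between = x$df_between,
    df_within = x$df_within,
    p_value = x$p_value
  )
}
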