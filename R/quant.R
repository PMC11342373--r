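#' Internal-standard response ratio
#'
#' Analyte quantifier area divided by the quantifier area of its assigned
#' (isotopically labeled) internal standard. Because the internal standard
#' experiences the same preparation losses and ionization matrix effects as
#' the analyte, the ratio is robust to both.
#'
#' @param analyte_area Analyte quantifier peak area.
#' @param is_area Internal-standard quantifier peak area (> 0).
#' @return Dimensionless response; `NA` with a warning where the IS area is
#'   not positive (quantification impossible for that sample-analyte).
#' @examples
#' response_ratio(0.5, 1.0)
#' @export
response_ratio <- function(analyte_area, is_area) {
  bad <- !(is_area > 0)
  if (any(bad, na.rm = TRUE)) {
    warning("internal-standard area not positive for ",
            sum(bad, na.rm = TRUE), " record(s); response set to NA")
  }
  ifelse(bad, NA_real_, analyte_area / is_area)
}

#' Average procedural-blank response per analyte
#'
#' Arithmetic mean of the response ratios measured in the procedural blanks
#' of a batch; this average is subtracted from every sample response to
#' correct for contamination from reagents, consumables and the laboratory
#' environment.
#'
#' @param blank_records Tibble with `analyte_id` and `response` columns, one
#'   row per procedural blank x analyte.
#' @return Tibble (analyte_id, blank_response, n_blanks). A single blank
#'   triggers a warning (duplicates are the intended practice); an empty
#'   input returns an empty table with a warning (correction skipped).
#' @examples
#' average_blank_response(tibble::tibble(
#'   analyte_id = c("PFOA", "PFOA"), response = c(0.010, 0.014)))
#' @export
average_blank_response <- function(blank_records) {
  if (nrow(blank_records) == 0) {
    warning("no procedural blanks: blank correction will be skipped")
    return(tibble::tibble(analyte_id = character(), blank_response = numeric(),
                          n_blanks = integer()))
  }
  out <- blank_records |>
    dplyr::summarise(
      blank_response = mean(.data$response, na.rm = TRUE),
      n_blanks = sum(!is.na(.data$response)),
      .by = "analyte_id"
    )
  if (any(out$n_blanks < 2)) {
    warning("fewer than 2 procedural blanks for some analytes; ",
            "blank correction based on a single measurement")
  }
  out
}

#' Subtract the average blank response
#'
#' @param response Sample response ratio(s).
#' @param blank_response Average procedural-blank response for the analyte.
#' @return Corrected response; negative values are retained (downstream
#'   reporting flags them) rather than clipped, so that validation
#'   statistics near the blank level stay unbiased.
#' @examples
#' blank_correct(0.105, 0.012)
#' @export
blank_correct <- function(response, blank_response) {
  response - blank_response
}

#' Fit a matrix-fortified standard calibration line
#'
#' Weighted linear least squares of blank-corrected response versus nominal
#' fortification level over one concentration segment. Weights are 1/x
#' (x = level in ng/kg); the 0 level enters with unit weight and informs the
#' intercept. The fitted object also stores the confirmation reference
#' values derived from the same calibrants: the mean ion ratio
#' (qualifier/quantifier) and mean relative retention time over calibrants
#' whose qualifier has S/N >= `qual_min_snr` (low levels would otherwise
#' corrupt the reference).
#'
#' @param calibrant_records Tibble with columns `conc` (nominal level,
#'   ng/kg), `response` (blank-corrected), and optionally `ion_ratio`,
#'   `rrt`, `snr_qual` for the reference values.
#' @param segment Numeric `c(low, high)` in ng/kg; only levels inside (and
#'   including) the bounds are fitted.
#' @param analyte_id Carried into the model for reporting.
#' @param qual_min_snr Qualifier usability threshold for reference values.
#' @return An `mfs_calibration` object with elements slope, intercept,
#'   segment, weighting, ref_ion_ratio, ref_rrt, n_points, data. Supports
#'   [generics::tidy()], [generics::glance()] and [ggplot2::autoplot()].
#' @examples
#' cal <- tibble::tibble(conc = c(0, 1, 5, 10, 50, 100),
#'                       response = 0.01 * c(0, 1, 5, 10, 50, 100))
#' fit_mfs_calibration(cal, segment = c(0, 100))
#' @export
fit_mfs_calibration <- function(calibrant_records, segment,
                                analyte_id = NA_character_,
                                qual_min_snr = 3) {
  stopifnot(length(segment) == 2, segment[1] < segment[2])
  dat <- dplyr::filter(
    calibrant_records,
    .data$conc >= segment[1], .data$conc <= segment[2],
    !is.na(.data$response)
  )
  if (nrow(dat) < 5) {
    stop("need >= 5 usable calibration levels inside the segment, got ",
         nrow(dat))
  }
  if (stats::sd(dat$response) == 0) {
    stop("degenerate calibration: all responses identical")
  }
  w <- ifelse(dat$conc > 0, 1 / dat$conc, 1)
  fit <- stats::lm(response ~ conc, data = dat, weights = w)
  coefs <- stats::coef(fit)

  ref <- list(ion_ratio = NA_real_, rrt = NA_real_)
  if (all(c("ion_ratio", "snr_qual") %in% names(calibrant_records))) {
    ok <- calibrant_records$snr_qual >= qual_min_snr &
      !is.na(calibrant_records$ion_ratio)
    if (any(ok, na.rm = TRUE)) {
      ref$ion_ratio <- mean(calibrant_records$ion_ratio[which(ok)])
    }
  }
  if (all(c("rrt", "snr_qual") %in% names(calibrant_records))) {
    ok <- calibrant_records$snr_qual >= qual_min_snr &
      !is.na(calibrant_records$rrt)
    if (any(ok, na.rm = TRUE)) {
      ref$rrt <- mean(calibrant_records$rrt[which(ok)])
    }
  }

  structure(
    list(
      analyte_id = analyte_id,
      slope = unname(coefs["conc"]),
      intercept = unname(coefs["(Intercept)"]),
      segment = segment,
      weighting = "1/x",
      ref_ion_ratio = ref$ion_ratio,
      ref_rrt = ref$rrt,
      n_points = nrow(dat),
      r_squared = suppressWarnings(summary(fit)$r.squared),
      data = dat
    ),
    class = "mfs_calibration"
  )
}

#' @export
print.mfs_calibration <- function(x, ...) {
  cat(sprintf(
    "<mfs_calibration> %s: response = %.4g + %.4g * conc on [%g, %g] ng/kg (%d levels, %s weights)\n",
    x$analyte_id, x$intercept, x$slope, x$segment[1], x$segment[2],
    x$n_points, x$weighting
  ))
  invisible(x)
}

#' Choose the calibration segment for a preliminary concentration
#'
#' The calibration ladder spans four decades, so quantification uses one of
#' two overlapping straight segments: the lower end (0-100 ng/kg) or the
#' higher end (50-2000 ng/kg), chosen from a provisional full-range
#' estimate. Concentrations above the top level are quantified on the high
#' segment with an extrapolation flag.
#'
#' @param preliminary_conc Provisional concentration (ng/kg, >= 0 expected).
#' @param mfs_levels The calibration levels (ng/kg).
#' @param split Concentration at which the high segment takes over.
#' @return List(segment = c(low, high), extrapolated = logical).
#' @examples
#' select_segment(5)$segment
#' select_segment(600)$segment
#' @export
select_segment <- function(preliminary_conc,
                           mfs_levels = mfs_levels_default(),
                           split = 100) {
  top <- max(mfs_levels)
  if (is.na(preliminary_conc) || preliminary_conc <= split) {
    list(segment = c(0, split), extrapolated = FALSE)
  } else {
    list(segment = c(50, top), extrapolated = preliminary_conc > top)
  }
}

#' Invert a calibration model
#'
#' @param corrected_response Blank-corrected response ratio(s).
#' @param model An `mfs_calibration`.
#' @return Concentration(s) in ng/kg; negative values are retained for
#'   unbiased statistics and flagged downstream.
#' @examples
#' m <- structure(list(slope = 0.02, intercept = 0.001),
#'                class = "mfs_calibration")
#' quantify(0.101, m)
#' @export
quantify <- function(corrected_response, model) {
  if (!is.finite(model$slope) || model$slope <= 0) {
    stop("calibration slope must be positive to quantify")
  }
  (corrected_response - model$intercept) / model$slope
}
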