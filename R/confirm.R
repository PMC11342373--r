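#' Ion ratio of a detection
#'
#' Relative abundance of the two diagnostic ions: qualifier peak area
#' divided by quantifier peak area. For single-product analytes (PFPeA-like)
#' the pseudo transition (precursor -> precursor) plays the qualifier role,
#' which deviates from confirmation guidance and is flagged as such in the
#' verdict.
#'
#' @param qualifier_area Qualifier (or pseudo) transition area.
#' @param quantifier_area Quantifier transition area (> 0).
#' @return Dimensionless ratio; `NA` where the quantifier is absent.
#' @examples
#' ion_ratio(0.30, 1.00)
#' @export
ion_ratio <- function(qualifier_area, quantifier_area) {
  ifelse(quantifier_area > 0, qualifier_area / quantifier_area, NA_real_)
}

#' Relative deviation from a reference value, in percent
#'
#' @param observed Observed value(s).
#' @param reference Reference value (> 0).
#' @return `|observed - reference| / reference * 100`.
#' @examples
#' relative_deviation(0.39, 0.30)
#' @export
relative_deviation <- function(observed, reference) {
  if (any(reference <= 0, na.rm = TRUE)) {
    stop("reference must be positive")
  }
  abs(observed - reference) / reference * 100
}

#' Identity confirmation verdicts
#'
#' Confirms or rejects each detection by comparing its ion ratio and
#' relative retention time against the references derived from the
#' matrix-fortified standard calibrants. A detection is confirmed when the
#' ion-ratio deviation is at most `ion_ratio_tol` percent AND the relative
#' retention-time deviation is at most `rrt_tol` percent; both bounds are
#' inclusive ("not deviate more than" is read literally). Records whose
#' references are unavailable receive a `not-assessable` reason; records
#' confirmed through a pseudo transition carry a `pseudo-ratio` caveat (the
#' verdict still counts, but it does not meet two-diagnostic-ion guidance).
#'
#' @param verdict_inputs Tibble with columns `ion_ratio`, `rrt`,
#'   `ref_ion_ratio`, `ref_rrt` and optionally `sample_id`, `analyte_id`,
#'   `area_quant`, `is_pseudo`.
#' @param thresholds List with `ion_ratio` (max deviation, percent; default
#'   30) and `rrt` (max deviation, percent; default 1).
#' @return The input with columns `ion_ratio_dev`, `rrt_dev`, `confirmed`,
#'   `reasons` (comma-separated failure labels, `""` when confirmed) and
#'   `caveat` appended.
#' @examples
#' check_confirmation(tibble::tibble(
#'   ion_ratio = 0.36, rrt = 1.005, ref_ion_ratio = 0.30, ref_rrt = 1.0))
#' @export
check_confirmation <- function(verdict_inputs,
                               thresholds = list(ion_ratio = 30, rrt = 1)) {
  vi <- verdict_inputs
  if (!"is_pseudo" %in% names(vi)) vi$is_pseudo <- FALSE
  if (!"area_quant" %in% names(vi)) vi$area_quant <- 1

  vi$ion_ratio_dev <- ifelse(
    !is.na(vi$ref_ion_ratio) & vi$ref_ion_ratio > 0 & !is.na(vi$ion_ratio),
    abs(vi$ion_ratio - vi$ref_ion_ratio) / vi$ref_ion_ratio * 100,
    NA_real_
  )
  vi$rrt_dev <- ifelse(
    !is.na(vi$ref_rrt) & vi$ref_rrt > 0 & !is.na(vi$rrt),
    abs(vi$rrt - vi$ref_rrt) / vi$ref_rrt * 100,
    NA_real_
  )

  no_quant <- !(vi$area_quant > 0) | is.na(vi$area_quant)
  no_ref <- is.na(vi$ref_ion_ratio) | is.na(vi$ref_rrt)
  # inclusive bounds with a float guard so that exact-boundary deviations
  # (e.g. an observed 1.01 against reference 1.00) pass as intended
  eps <- 1e-9
  ir_fail <- !is.na(vi$ion_ratio_dev) &
    vi$ion_ratio_dev > thresholds$ion_ratio + eps
  rrt_fail <- !is.na(vi$rrt_dev) & vi$rrt_dev > thresholds$rrt + eps
  missing_obs <- !no_quant & !no_ref &
    (is.na(vi$ion_ratio_dev) | is.na(vi$rrt_dev))

  vi$confirmed <- !no_quant & !no_ref & !missing_obs & !ir_fail & !rrt_fail
  vi$reasons <- purrr::pmap_chr(
    list(no_quant, no_ref, missing_obs, ir_fail, rrt_fail),
    function(nq, nr, mo, ir, rr) {
      paste(c(
        if (nq) "no-quantifier",
        if (nr) "not-assessable",
        if (mo) "missing-observation",
        if (ir) "ion-ratio",
        if (rr) "rrt"
      ), collapse = ",")
    }
  )
  vi$caveat <- ifelse(vi$is_pseudo & vi$confirmed, "pseudo-ratio", "")
  vi
}

#' Confirm all detections of a quantified batch
#'
#' Applies [check_confirmation()] to every sample x analyte record of a
#' [quantify_batch()] result, using the reference ion ratio and relative
#' retention time stored on each analyte's calibration model.
#'
#' @param quant A `pfas_quant` object.
#' @param thresholds See [check_confirmation()].
#' @return The `results` tibble of `quant` with verdict columns appended.
#' @export
confirm_batch <- function(quant, thresholds = list(ion_ratio = 30, rrt = 1)) {
  stopifnot(inherits(quant, "pfas_quant"))
  refs <- purrr::map_dfr(quant$models, function(m) {
    tibble::tibble(
      analyte_id = m$low$analyte_id,
      ref_ion_ratio = m$low$ref_ion_ratio,
      ref_rrt = m$low$ref_rrt
    )
  })
  quant$results |>
    dplyr::left_join(refs, by = "analyte_id") |>
    check_confirmation(thresholds)
}
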