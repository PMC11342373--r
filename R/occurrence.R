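#' Analytes covered by the EFSA tolerable-weekly-intake sum
#' @export
efsa4 <- function() c("PFOA", "PFNA", "PFHxS", "PFOS")

#' Detection and confirmation decision for one result
#'
#' A substance is reported present (detected) only when its concentration
#' strictly exceeds the LOQ — results at or below the LOQ report absence —
#' and reported confirmed when it is detected and the identity verdict
#' passed.
#'
#' @param conc Quantified concentration (ng/kg).
#' @param loq Limit of quantification (ng/kg); `NA` makes the record not
#'   assessable.
#' @param confirmed Logical identity verdict.
#' @return Tibble (detected, confirmed, assessable).
#' @examples
#' detect_decision(2.0, 0.5, FALSE)
#' @export
detect_decision <- function(conc, loq, confirmed) {
  assessable <- !is.na(loq)
  detected <- assessable & !is.na(conc) & conc > loq
  tibble::tibble(
    detected = detected,
    confirmed = detected & confirmed %in% TRUE,
    assessable = assessable
  )
}

#' Detection frequency per matrix category
#'
#' Fraction of samples in each category with at least one confirmed analyte;
#' a sample counts once however many analytes confirm in it.
#'
#' @param records Tibble with `sample_id`, `category` and `confirmed`
#'   columns (one row per sample x analyte).
#' @return Tibble (category, n_samples, n_with_confirmed, fraction).
#' @export
frequency_by_category <- function(records) {
  if (nrow(records) == 0) stop("no records")
  records |>
    dplyr::summarise(
      any_confirmed = any(.data$confirmed %in% TRUE),
      .by = c("category", "sample_id")
    ) |>
    dplyr::summarise(
      n_samples = dplyr::n(),
      n_with_confirmed = sum(.data$any_confirmed),
      fraction = sum(.data$any_confirmed) / dplyr::n(),
      .by = "category"
    )
}

#' Lower- and upper-bound sums over an analyte subset
#'
#' Per sample, sums the concentrations of a subset of analytes (default the
#' EFSA-4) under the two censoring conventions used in exposure assessment:
#' the lower bound sets non-detects to zero, the upper bound sets them to
#' their LOQ. Lower LOQs therefore directly shrink upper-bound exposure
#' estimates.
#'
#' @param records Tibble with `sample_id`, `analyte_id`, `conc`, `detected`
#'   columns (one row per sample x analyte).
#' @param subset Analyte ids to sum (default [efsa4()]).
#' @param loqs Tibble (analyte_id, loq) or a named vector of LOQs covering
#'   the subset.
#' @return Tibble (sample_id, lower_bound, upper_bound) in ng/kg.
#' @examples
#' rec <- tibble::tibble(sample_id = "s", analyte_id = efsa4(),
#'                       conc = c(10, NA, NA, 2),
#'                       detected = c(TRUE, FALSE, FALSE, TRUE))
#' bound_sums(rec, loqs = c(PFOA = 1, PFNA = 1, PFHxS = 0.5, PFOS = 0.5))
#' @export
bound_sums <- function(records, subset = efsa4(), loqs) {
  if (!is.data.frame(loqs)) {
    loqs <- tibble::tibble(analyte_id = names(loqs), loq = unname(loqs))
  }
  missing <- setdiff(subset, loqs$analyte_id)
  if (length(missing)) {
    stop("missing LOQ for subset analyte(s): ", paste(missing, collapse = ", "))
  }
  records |>
    dplyr::filter(.data$analyte_id %in% subset) |>
    dplyr::left_join(loqs[, c("analyte_id", "loq")], by = "analyte_id") |>
    dplyr::summarise(
      lower_bound = sum(ifelse(.data$detected, .data$conc, 0)),
      upper_bound = sum(ifelse(.data$detected, .data$conc, .data$loq)),
      .by = "sample_id"
    )
}
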