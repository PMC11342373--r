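#' S/N-based limit of quantification
#'
#' Used when no substantial signal is seen in the procedural blanks: the LOQ
#' is the lowest nonzero matrix-fortified standard level whose quantifier
#' peak reaches a signal-to-noise ratio of at least `snr_min` (default 6).
#'
#' @param mfs_peak_results Tibble with columns `conc` (nominal level, ng/kg)
#'   and `snr` (quantifier signal-to-noise at that level).
#' @param snr_min Minimum acceptable S/N.
#' @return List(loq, flag): `loq` in ng/kg, or `NA` with flag
#'   `"undeterminable"` when no level qualifies.
#' @examples
#' loq_snr_strategy(tibble::tibble(conc = c(0.5, 1), snr = c(8, 20)))
#' @export
loq_snr_strategy <- function(mfs_peak_results, snr_min = 6) {
  ok <- mfs_peak_results |>
    dplyr::filter(.data$conc > 0, !is.na(.data$snr), .data$snr >= snr_min)
  if (nrow(ok) == 0) {
    return(list(loq = NA_real_, flag = "undeterminable"))
  }
  list(loq = min(ok$conc), flag = "")
}

#' Blank-based limit of quantification (raw)
#'
#' Used when the procedural blanks carry a substantial signal: the raw LOQ
#' is 3.3 times the analyte concentration measured in the procedural blank.
#'
#' @param blank_conc Procedural-blank concentration (ng/kg, > 0).
#' @param factor Multiplier (default 3.3).
#' @return Raw LOQ in ng/kg (snap it to the calibration grid with
#'   [snap_to_level()]).
#' @examples
#' loq_blank_strategy(5)    # 16.5
#' @export
loq_blank_strategy <- function(blank_conc, factor = 3.3) {
  if (any(blank_conc <= 0)) stop("blank concentration must be positive")
  factor * blank_conc
}

#' Snap a raw LOQ up to the calibration grid
#'
#' Reported LOQs sit on the matrix-fortified calibration grid (results at or
#' below the LOQ are reported as absent, and the next calibration level up
#' is the lowest level at which quantification is actually supported), so a
#' raw 3.3x-blank LOQ is rounded up to the smallest level that is at least
#' as large.
#'
#' @param raw_loq Raw LOQ (ng/kg, > 0).
#' @param mfs_levels Calibration levels (ng/kg).
#' @return List(loq, flag): flag `"above-calibration"` when the raw value
#'   exceeds the top level (the top level is returned).
#' @examples
#' snap_to_level(16.5)  # 25
#' snap_to_level(1.65)  # 2.5
#' @export
snap_to_level <- function(raw_loq, mfs_levels = mfs_levels_default()) {
  stopifnot(raw_loq > 0)
  lv <- sort(mfs_levels[mfs_levels > 0])
  if (raw_loq > max(lv)) {
    return(list(loq = max(lv), flag = "above-calibration"))
  }
  list(loq = min(lv[lv >= raw_loq]), flag = "")
}

#' Limit of confirmation
#'
#' The LOC is the lowest matrix-fortified standard level at which the
#' identity-confirmation criteria are met; when that level lies below the
#' LOQ, the LOC is set equal to the LOQ (a result cannot be confirmed where
#' it cannot even be quantified).
#'
#' @param confirmation_by_level Tibble with columns `conc` (nonzero MFS
#'   level, ng/kg) and `confirmed` (logical).
#' @param loq The analyte's LOQ (ng/kg).
#' @return List(loc, flag): flag `"undeterminable"` when no level confirms.
#' @examples
#' determine_loc(tibble::tibble(conc = c(0.5, 2.5), confirmed = c(FALSE, TRUE)),
#'               loq = 0.5)
#' @export
determine_loc <- function(confirmation_by_level, loq) {
  ok <- dplyr::filter(confirmation_by_level, .data$conc > 0, .data$confirmed)
  if (nrow(ok) == 0) {
    return(list(loc = NA_real_, flag = "undeterminable"))
  }
  list(loc = max(min(ok$conc), loq), flag = "")
}

#' Blank-contribution check
#'
#' The blank level must not exceed 30% of the level found in the samples of
#' the accompanying batch; exactly 30% passes (inclusive bound).
#'
#' @param blank_level Blank concentration (ng/kg, >= 0).
#' @param sample_conc Sample concentration (ng/kg, >= 0).
#' @param max_fraction Maximum allowed blank/sample ratio (default 0.30).
#' @return Logical: `TRUE` = pass, `FALSE` = flag.
#' @examples
#' blank_contribution_check(3, 10)   # TRUE (exactly 30%)
#' blank_contribution_check(4, 10)   # FALSE
#' @export
blank_contribution_check <- function(blank_level, sample_conc,
                                     max_fraction = 0.30) {
  stopifnot(all(blank_level >= 0), all(sample_conc >= 0))
  blank_level <= max_fraction * sample_conc
}

#' Reconcile a determined LOQ with the spiked validation results
#'
#' The MFS-derived LOQ comes from a single matrix; it is assessed against
#' the spiked validation samples and raised when unachievable there. If the
#' lowest spike level at or above the LOQ fails the recovery/precision
#' criteria, the LOQ is raised to the next spike level that passes, with a
#' flag.
#'
#' @param loq Determined LOQ (ng/kg).
#' @param validation_results Tibble with `spike_level`, `recovery_mean`,
#'   `rsd_rl` for the analyte.
#' @param criteria List(recovery = c(65, 135), rsd_rl_max = 25).
#' @return List(loq, flag): flag `"raised"` when adjusted, `"unassessed"`
#'   when no spiked data is available, `""` otherwise.
#' @export
assess_loq_against_validation <- function(loq, validation_results,
                                          criteria = list(recovery = c(65, 135),
                                                          rsd_rl_max = 25)) {
  if (is.na(loq)) return(list(loq = loq, flag = "unassessed"))
  vr <- dplyr::filter(validation_results, .data$spike_level >= loq) |>
    dplyr::arrange(.data$spike_level)
  if (nrow(vr) == 0) return(list(loq = loq, flag = "unassessed"))
  passes <- vr$recovery_mean >= criteria$recovery[1] &
    vr$recovery_mean <= criteria$recovery[2] &
    vr$rsd_rl <= criteria$rsd_rl_max
  if (passes[1]) return(list(loq = loq, flag = ""))
  nxt <- which(passes)
  if (length(nxt) == 0) {
    return(list(loq = NA_real_, flag = "no-passing-level"))
  }
  list(loq = vr$spike_level[nxt[1]], flag = "raised")
}

#' Determine LOQ and LOC for every analyte of a batch
#'
#' Applies the two-branch LOQ rule per analyte: when the procedural-blank
#' concentration is substantial (greater than `blank_substantial_frac`
#' times the lowest nonzero calibration level), the LOQ is 3.3x the blank
#' concentration snapped up to the calibration grid; otherwise it is the
#' lowest calibration level with quantifier S/N >= `snr_min`. The LOC is the
#' lowest confirming calibration level, floored at the LOQ. Each analyte
#' also gets a blank-contribution flag relative to the given LOQ-level
#' samples.
#'
#' @param confirmed A confirmed results tibble from [confirm_batch()] (must
#'   contain the `mfs_calibrant` rows with `spike_level_ng_kg`, `snr_quant`,
#'   `conc`, `confirmed`) .
#' @param snr_min S/N threshold for the no-blank branch.
#' @param blank_factor Multiplier for the blank branch (default 3.3).
#' @param blank_substantial_frac Substantiality threshold: blank
#'   concentration above this fraction of the lowest nonzero MFS level
#'   selects the blank branch (default 0.3).
#' @param mfs_levels Calibration grid (taken from the data when `NULL`).
#' @return Tibble: analyte_id, category, blank_conc, loq_strategy, loq_raw,
#'   loq, loc, flags.
#' @export
determine_limits <- function(confirmed, snr_min = 6, blank_factor = 3.3,
                             blank_substantial_frac = 0.3,
                             mfs_levels = NULL) {
  calib <- dplyr::filter(confirmed, .data$role == "mfs_calibrant")
  if (is.null(mfs_levels)) {
    mfs_levels <- sort(unique(calib$spike_level_ng_kg))
  }
  lowest <- min(mfs_levels[mfs_levels > 0])
  blank_col <- if ("conc_uncorrected" %in% names(confirmed)) {
    "conc_uncorrected"
  } else {
    "conc"
  }
  blanks <- confirmed |>
    dplyr::filter(.data$role == "procedural_blank") |>
    dplyr::summarise(blank_conc = mean(.data[[blank_col]]),
                     .by = "analyte_id")

  calib |>
    dplyr::left_join(blanks, by = "analyte_id") |>
    dplyr::group_by(.data$analyte_id, category = .data$matrix_category) |>
    dplyr::group_modify(function(d, key) {
      bc <- d$blank_conc[1]
      if (is.na(bc)) bc <- 0
      flags <- character()
      if (bc > blank_substantial_frac * lowest) {
        strategy <- "blank_based"
        raw <- loq_blank_strategy(bc, blank_factor)
        sn <- snap_to_level(raw, mfs_levels)
        loq <- sn$loq
        if (nzchar(sn$flag)) flags <- c(flags, sn$flag)
      } else {
        strategy <- "snr_based"
        res <- loq_snr_strategy(
          tibble::tibble(conc = d$spike_level_ng_kg, snr = d$snr_quant),
          snr_min
        )
        raw <- res$loq
        loq <- res$loq
        if (nzchar(res$flag)) flags <- c(flags, res$flag)
      }
      loc_res <- determine_loc(
        tibble::tibble(conc = d$spike_level_ng_kg, confirmed = d$confirmed),
        loq = loq
      )
      if (nzchar(loc_res$flag)) flags <- c(flags, paste0("loc-", loc_res$flag))
      tibble::tibble(
        blank_conc = bc, loq_strategy = strategy, loq_raw = raw,
        loq = loq, loc = loc_res$loc,
        flags = paste(flags, collapse = ",")
      )
    }) |>
    dplyr::ungroup()
}
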