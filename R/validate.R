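#' Apparent recovery (trueness) of a spiked sample
#'
#' Calculated concentration divided by the actual spiked concentration,
#' after subtracting any baseline found in the procedural blank or the
#' unspiked sample, expressed in percent.
#'
#' @param calculated_conc Quantified concentration (ng/kg).
#' @param spike_conc Spiked concentration (ng/kg, > 0).
#' @param baseline_conc Baseline to subtract (ng/kg, default 0).
#' @return Percent recovery.
#' @examples
#' apparent_recovery(51.5, 50)      # 103
#' apparent_recovery(55, 50, 5)     # 100
#' @export
apparent_recovery <- function(calculated_conc, spike_conc, baseline_conc = 0) {
  if (any(spike_conc <= 0)) stop("spike concentration must be positive")
  (calculated_conc - baseline_conc) / spike_conc * 100
}

#' Relative standard deviation, in percent
#'
#' Sample (n-1) standard deviation over the absolute mean, times 100.
#'
#' @param values Numeric vector, length >= 2, nonzero mean.
#' @return Percent RSD.
#' @examples
#' rsd(c(90, 100, 110))   # 10
#' @export
rsd <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) stop("need at least 2 values for an RSD")
  m <- mean(values)
  if (m == 0) stop("RSD undefined for zero mean")
  stats::sd(values) / abs(m) * 100
}

#' Aggregate per-sample results into validation summaries
#'
#' For each analyte and spike level: the mean apparent recovery over all
#' spiked samples, the repeatability RSD (`rsd_r`) pooled over the matrices
#' within each category (note: pooling different matrices overestimates
#' true repeatability; this is deliberate, stressing the method across a
#' wide matrix range), the within-laboratory reproducibility RSD (`rsd_rl`)
#' over all matrices of all categories, and the count of samples passing
#' identity confirmation.
#'
#' Baseline correction per sample uses the unspiked result of the same
#' matrix when that result exceeds the analyte's LOQ, else the
#' procedural-blank concentration (both optional inputs).
#'
#' @param confirmed Results tibble from [confirm_batch()] (may combine
#'   several categories/batches); needs roles `spiked` and optionally
#'   `unknown` plus `conc`, `confirmed`.
#' @param loqs Optional tibble (analyte_id, category, loq) used for the
#'   unspiked-baseline rule.
#' @return Tibble: analyte_id, spike_level, n_samples, n_confirmed,
#'   recovery_mean, rsd_rl, and a nested per-category `rsd_r` table plus
#'   the pooled `rsd_r` (mean over categories).
#' @export
aggregate_validation <- function(confirmed, loqs = NULL) {
  spiked <- dplyr::filter(confirmed, .data$role == "spiked")
  if (nrow(spiked) == 0) stop("no spiked samples to aggregate")

  base <- confirmed |>
    dplyr::filter(.data$role == "unknown") |>
    dplyr::select("analyte_id", "matrix_category", "matrix_name",
                  baseline_conc = "conc")
  if (!is.null(loqs)) {
    base <- base |>
      dplyr::left_join(
        dplyr::rename(loqs, matrix_category = "category"),
        by = c("analyte_id", "matrix_category")
      ) |>
      dplyr::mutate(
        baseline_conc = dplyr::if_else(
          !is.na(.data$loq) & .data$baseline_conc > .data$loq,
          .data$baseline_conc, 0
        )
      ) |>
      dplyr::select(-dplyr::any_of(c("loq", "loc")))
  } else {
    base$baseline_conc <- 0
  }

  spiked <- spiked |>
    dplyr::left_join(base,
                     by = c("analyte_id", "matrix_category", "matrix_name")) |>
    dplyr::mutate(
      baseline_conc = dplyr::coalesce(.data$baseline_conc, 0),
      recovery = apparent_recovery(.data$conc, .data$spike_level_ng_kg,
                                   .data$baseline_conc)
    )

  per_cat <- spiked |>
    dplyr::summarise(
      rsd_r = rsd(.data$recovery),
      .by = c("analyte_id", "spike_level_ng_kg", "matrix_category")
    )

  spiked |>
    dplyr::summarise(
      n_samples = dplyr::n(),
      n_confirmed = sum(.data$confirmed, na.rm = TRUE),
      recovery_mean = mean(.data$recovery),
      rsd_rl = rsd(.data$recovery),
      .by = c("analyte_id", "spike_level_ng_kg")
    ) |>
    dplyr::left_join(
      per_cat |>
        dplyr::summarise(rsd_r = mean(.data$rsd_r),
                         .by = c("analyte_id", "spike_level_ng_kg")),
      by = c("analyte_id", "spike_level_ng_kg")
    ) |>
    dplyr::rename(spike_level = "spike_level_ng_kg") |>
    dplyr::arrange(.data$analyte_id, .data$spike_level)
}

#' Classify analytes as quantitative or qualitative
#'
#' An analyte is fit for quantitative use (`quan`) when every evaluated
#' spike level satisfies both monitoring criteria — apparent recovery
#' within `criteria$recovery` (inclusive) and `rsd_rl` at most
#' `criteria$rsd_rl_max` (inclusive) — and qualitative-only (`qual`)
#' otherwise.
#'
#' @param summaries Validation summaries from [aggregate_validation()].
#' @param criteria List(recovery = c(65, 135), rsd_rl_max = 25).
#' @return Tibble (analyte_id, verdict) with verdict `"quan"` or `"qual"`.
#' @examples
#' classify(tibble::tibble(analyte_id = "PFOA", spike_level = 50,
#'                         recovery_mean = 103, rsd_rl = 8))
#' @export
classify <- function(summaries,
                     criteria = list(recovery = c(65, 135), rsd_rl_max = 25)) {
  summaries |>
    dplyr::summarise(
      verdict = dplyr::if_else(
        all(.data$recovery_mean >= criteria$recovery[1] &
              .data$recovery_mean <= criteria$recovery[2] &
              .data$rsd_rl <= criteria$rsd_rl_max),
        "quan", "qual"
      ),
      .by = "analyte_id"
    )
}

#' One-way ANOVA on internal-standard signal variability
#'
#' Single-factor fixed-effects ANOVA comparing groups of per-measurement
#' relative standard deviations of internal-standard signals (e.g. the
#' HFPO-DA internal standard versus those of PFOA and PFOS, to test for
#' degradation of HFPO-DA: degradation would inflate its signal variance
#' relative to the two persistent references).
#'
#' @param group_rsds Tibble with columns `group` and `value` (RSDs or
#'   signals), or a named list of numeric vectors.
#' @return A `stability_result`: list(f_statistic, p_value, df_between,
#'   df_within, group_labels, group_means, group_rsds).
#' @examples
#' anova_stability(list(a = c(1, 2, 3), b = c(1.5, 2.5, 3.5)))
#' @export
anova_stability <- function(group_rsds) {
  if (is.list(group_rsds) && !is.data.frame(group_rsds)) {
    group_rsds <- purrr::imap_dfr(
      group_rsds, ~ tibble::tibble(group = .y, value = .x)
    )
  }
  counts <- dplyr::count(group_rsds, .data$group)
  if (nrow(counts) < 2 || any(counts$n < 2)) {
    stop("need >= 2 groups with >= 2 values each")
  }
  ow <- stats::oneway.test(value ~ group, data = group_rsds, var.equal = TRUE)
  structure(
    list(
      f_statistic = unname(ow$statistic),
      p_value = unname(ow$p.value),
      df_between = unname(ow$parameter[1]),
      df_within = unname(ow$parameter[2]),
      group_labels = counts$group,
      group_means = tapply(group_rsds$value, group_rsds$group, mean),
      group_rsds = group_rsds
    ),
    class = "stability_result"
  )
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf(
    "<stability_result> one-way ANOVA: F(%g, %g) = %.4g, p = %.4g\n",
    x$df_between, x$df_within, x$f_statistic, x$p_value
  ))
  invisible(x)
}

#' Ionization matrix effect, in percent
#'
#' Injection-standard area in a matrix extract over its area in the
#' procedural blank, times 100; below 100 is suppression, above 100 is
#' enhancement. Only determinable for compounds with a labeled analogue in
#' the injection-standard mix.
#'
#' @param injstd_area_matrix Injection-standard area in the matrix sample.
#' @param injstd_area_blank Injection-standard area in the procedural blank
#'   (> 0).
#' @return Percent matrix effect.
#' @examples
#' matrix_effect(0.32, 1.00)   # 32
#' @export
matrix_effect <- function(injstd_area_matrix, injstd_area_blank) {
  if (any(injstd_area_blank <= 0)) stop("blank injection-standard area must be positive")
  injstd_area_matrix / injstd_area_blank * 100
}

#' Absolute preparation recovery, in percent
#'
#' Ratio of internal standard (added before preparation) to injection
#' standard (added after cleanup) in a sample, relative to the same ratio in
#' a reference where the internal standard was added after cleanup (or its
#' nominal expectation). Separates preparation losses from ionization
#' effects, which cancel in the ratio.
#'
#' @param is_over_injstd_sample IS/injection-standard area ratio in the
#'   sample.
#' @param is_over_injstd_reference Reference ratio (> 0).
#' @return Percent absolute recovery.
#' @examples
#' absolute_recovery(0.41, 1.00)   # 41
#' @export
absolute_recovery <- function(is_over_injstd_sample, is_over_injstd_reference) {
  if (any(is_over_injstd_reference <= 0)) stop("reference ratio must be positive")
  is_over_injstd_sample / is_over_injstd_reference * 100
}
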