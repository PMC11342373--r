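#' Default pipeline configuration
#'
#' Collects every threshold the pipeline applies, at its guidance default:
#' ion-ratio deviation 30%, relative-retention-time deviation 1%,
#' signal-to-noise minimum 6, blank LOQ factor 3.3, apparent recovery
#' 65-135%, within-laboratory reproducibility RSD at most 25%.
#'
#' @param categories Matrix categories to simulate/process.
#' @param seed Master seed; each category batch derives its own seed from
#'   it.
#' @param noise_cv Measurement noise CV for simulation.
#' @param thresholds Named list overriding individual thresholds.
#' @return A `run_config` list.
#' @export
default_run_config <- function(categories = pfas_categories(),
                               seed = 1L,
                               noise_cv = 0.10,
                               thresholds = list()) {
  th <- utils::modifyList(
    list(
      ion_ratio = 30, rrt = 1, snr_min = 6, blank_factor = 3.3,
      recovery = c(65, 135), rsd_rl_max = 25,
      blank_contribution_frac = 0.30, qual_min_snr = 3
    ),
    thresholds
  )
  stopifnot(
    th$ion_ratio > 0, th$rrt > 0, th$snr_min > 0, th$blank_factor > 0,
    all(th$recovery > 0), th$rsd_rl_max > 0
  )
  structure(
    list(categories = categories, seed = as.integer(seed),
         noise_cv = noise_cv, thresholds = th),
    class = "run_config"
  )
}

#' Run the full pipeline on simulated batches
#'
#' For each configured matrix category: designs a one-day validation batch,
#' simulates its peak table, quantifies it (response ratios, blank
#' correction, segmented calibration), confirms identities, determines LOQ
#' and LOC, and finally pools all categories into validation summaries,
#' quantitative/qualitative verdicts and an occurrence summary of the
#' spiked/unknown samples. Fully deterministic for a fixed seed.
#'
#' @param config A `run_config` from [default_run_config()].
#' @param panel A `pfas_panel` (default [build_default_panel()]).
#' @param params Optional `generation_params`; defaults derive from `panel`
#'   and `config$noise_cv`.
#' @return A `pfas_report` list: `results` (all sample x analyte records
#'   with concentrations and verdicts), `limits`, `validation`, `verdicts`,
#'   `occurrence`, `blank_log`, `config`.
#' @examples
#' \donttest{
#' rep <- run_pipeline(default_run_config(categories = "fruit", seed = 1))
#' rep$validation
#' }
#' @export
run_pipeline <- function(config = default_run_config(),
                         panel = build_default_panel(),
                         params = NULL) {
  stopifnot(inherits(config, "run_config"))
  th <- config$thresholds
  if (is.null(params)) {
    params <- default_generation_params(panel, noise_cv = config$noise_cv)
  }

  per_cat <- purrr::imap(
    stats::setNames(config$categories, config$categories),
    function(cat, idx) {
      cat_seed <- config$seed + 1000L * match(cat, pfas_categories())
      design <- design_validation_batch(cat, seed = cat_seed)
      pt <- simulate_peak_table(design, params, panel)
      q <- quantify_batch(pt, panel, design$samples,
                          qual_min_snr = th$qual_min_snr)
      conf <- confirm_batch(
        q, thresholds = list(ion_ratio = th$ion_ratio, rrt = th$rrt)
      )
      lim <- determine_limits(conf, snr_min = th$snr_min,
                              blank_factor = th$blank_factor,
                              mfs_levels = design$mfs_levels)
      list(confirmed = conf, limits = lim, blank_log = q$blank_log,
           design = design)
    }
  )

  confirmed <- purrr::map_dfr(per_cat, "confirmed")
  limits <- purrr::map_dfr(per_cat, "limits")
  blank_log <- purrr::imap_dfr(
    per_cat, ~ dplyr::mutate(.x$blank_log, category = .y)
  )

  validation <- aggregate_validation(
    confirmed, loqs = limits[, c("analyte_id", "category", "loq")]
  )
  # spike levels below the analyte's LOQ report absence, so they carry no
  # quantitative-performance weight; classify on levels >= the largest
  # category LOQ (inclusive)
  max_loq <- limits |>
    dplyr::summarise(
      loq_max = ifelse(all(is.na(.data$loq)), 0, max(.data$loq, na.rm = TRUE)),
      .by = "analyte_id"
    )
  validation <- validation |>
    dplyr::left_join(max_loq, by = "analyte_id") |>
    dplyr::mutate(
      evaluated = .data$spike_level >= dplyr::coalesce(.data$loq_max, 0)
    ) |>
    dplyr::select(-"loq_max")
  verdicts <- classify(
    dplyr::filter(validation, .data$evaluated),
    criteria = list(recovery = th$recovery, rsd_rl_max = th$rsd_rl_max)
  )
  validation <- dplyr::left_join(validation, verdicts, by = "analyte_id")

  occ_records <- confirmed |>
    dplyr::filter(.data$role %in% c("spiked", "unknown")) |>
    dplyr::left_join(
      limits[, c("analyte_id", "category", "loq")],
      by = c("analyte_id", matrix_category = "category")
    ) |>
    dplyr::mutate(
      detect_decision(.data$conc, .data$loq, .data$confirmed)[
        , c("detected", "confirmed")] |>
        stats::setNames(c("detected", "occ_confirmed"))
    ) |>
    dplyr::rename(category = "matrix_category")
  occurrence <- frequency_by_category(
    dplyr::select(occ_records, "sample_id", "category",
                  confirmed = "occ_confirmed")
  )

  structure(
    list(results = confirmed, limits = limits, validation = validation,
         verdicts = verdicts, occurrence = occurrence,
         blank_log = blank_log, config = config),
    class = "pfas_report"
  )
}

#' @export
print.pfas_report <- function(x, ...) {
  cat("<pfas_report> ", length(unique(x$results$sample_id)), " samples, ",
      length(unique(x$results$analyte_id)), " analytes across ",
      length(x$config$categories), " categor",
      if (length(x$config$categories) == 1) "y" else "ies", "\n", sep = "")
  cat("  verdicts: ", sum(x$verdicts$verdict == "quan"), " quan / ",
      sum(x$verdicts$verdict == "qual"), " qual\n", sep = "")
  invisible(x)
}

#' Write a report bundle to a directory
#'
#' Writes the results, limits, validation, occurrence and blank-correction
#' tables of a [run_pipeline()] report as CSV files.
#'
#' @param report A `pfas_report`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(report, dir) {
  stopifnot(inherits(report, "pfas_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  out <- function(tbl, name) {
    readr::write_csv(
      dplyr::select(tbl, !dplyr::where(is.list)),
      file.path(dir, paste0(name, ".csv"))
    )
  }
  out(report$results, "results")
  out(report$limits, "limits")
  out(report$validation, "validation")
  out(report$occurrence, "occurrence")
  out(report$blank_log, "blank_log")
  invisible(dir)
}
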