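#' Simulate an integrated peak-area table for a batch
#'
#' Forward model of the measurement process: for each sample and each MRM
#' transition it generates the integrated peak area, apex retention time and
#' signal-to-noise ratio that the instrument's integration software would
#' report.
#'
#' The quantifier area of an analyte is
#' `(spike + endogenous + blank) * slope * recovery * matrix_effect * eps`,
#' with `eps` a unit-mean lognormal multiplier of CV `noise_cv`; qualifier
#' and pseudo transitions are scaled by their ion-fraction ratio to the
#' quantifier and draw independent noise. Internal standards are generated
#' at their nominal added level (default 5 ng/kg-equivalent) and share the
#' sample's recovery and matrix effect, which is what makes the response
#' ratio robust to both. Injection standards are added after cleanup and
#' therefore bypass the preparation recovery. Procedural blanks contain only
#' the contamination level and see neither matrix effect nor preparation
#' loss of a matrix.
#'
#' Retention times are the panel's expected values plus Gaussian jitter;
#' all transitions of one compound in one sample share the same jitter draw
#' (they are the same physical peak). The reported `snr` is the apex height
#' implied by the area and the configured Gaussian peak width, divided by
#' the configured baseline noise sd.
#'
#' @param design A `batch_design` from [design_validation_batch()]; its seed
#'   makes the table reproducible.
#' @param params A `generation_params` list, see [default_generation_params()].
#' @param panel A `pfas_panel`.
#' @return Tibble (sample_id, transition_id, area, rt, snr), one row per
#'   sample x transition.
#' @examples
#' panel <- build_default_panel()
#' d <- design_validation_batch("fruit", seed = 7)
#' pt <- simulate_peak_table(d, default_generation_params(panel), panel)
#' @export
simulate_peak_table <- function(design, params, panel) {
  stopifnot(inherits(design, "batch_design"), inherits(params, "generation_params"))
  category <- design$category
  if (!category %in% colnames(params$abs_recovery)) {
    stop("no abs_recovery parameters for category ", category)
  }
  if (!category %in% names(params$matrix_effect)) {
    stop("no matrix_effect parameter for category ", category)
  }

  an <- panel$analytes
  compound_rt <- c(
    stats::setNames(an$expected_rt, an$analyte_id),
    stats::setNames(panel$internal_standards$expected_rt,
                    panel$internal_standards$is_id),
    stats::setNames(panel$injection_standards$expected_rt,
                    panel$injection_standards$id)
  )
  missing_slope <- setdiff(names(compound_rt), names(params$response_slope))
  if (length(missing_slope)) {
    stop("missing response_slope for: ", paste(missing_slope, collapse = ", "))
  }

  quant_frac <- panel$transitions |>
    dplyr::filter(.data$role == "quantifier") |>
    dplyr::select("compound_id", quant_fraction = "true_ion_fraction")

  grid <- tidyr::expand_grid(
    design$samples[, c("sample_id", "role", "matrix_name", "spike_level_ng_kg")],
    dplyr::rename(panel$transitions, tr_role = "role")
  ) |>
    dplyr::left_join(quant_frac, by = "compound_id")

  is_analyte <- grid$compound_id %in% an$analyte_id
  is_injstd <- grid$compound_id %in% panel$injection_standards$id
  is_blank <- grid$role == "procedural_blank"

  # true concentration per row
  blank_of <- function(id) {
    out <- params$blank_level[id]
    out[is.na(out)] <- 0
    unname(out)
  }
  endo <- rep(0, nrow(grid))
  if (!is.null(params$endogenous)) {
    key <- paste(grid$compound_id, grid$matrix_name)
    ek <- paste(params$endogenous$analyte_id, params$endogenous$matrix_name)
    hit <- match(key, ek)
    endo[!is.na(hit)] <- params$endogenous$conc_ng_kg[hit[!is.na(hit)]]
  }
  conc <- ifelse(
    is_analyte,
    ifelse(is_blank,
      blank_of(grid$compound_id),
      grid$spike_level_ng_kg + endo + blank_of(grid$compound_id)
    ),
    params$is_nominal_ng_kg
  )

  rec <- params$abs_recovery[grid$compound_id, category]
  rec[is_blank | is_injstd] <- 1
  me <- ifelse(is_blank, 1, params$matrix_effect[[category]])

  # analyte_bias models a surrogate-IS mismatch between the calibration
  # matrix and the validation matrices, so it spares the MFS calibrants:
  # a bias shared by calibrants would be absorbed by the calibration line
  bias <- rep(1, nrow(grid))
  if (!is.null(params$analyte_bias)) {
    b <- params$analyte_bias[grid$compound_id]
    b[grid$role %in% c("mfs_calibrant", "procedural_blank")] <- NA
    bias[!is.na(b)] <- b[!is.na(b)]
  }

  cv <- rep(params$noise_cv, nrow(grid))
  if (!is.null(params$analyte_cv)) {
    acv <- params$analyte_cv[grid$compound_id]
    cv[!is.na(acv)] <- acv[!is.na(acv)]
  }

  slope <- params$response_slope[grid$compound_id]

  withr::with_seed(design$seed, {
    eps <- vapply(cv, function(x) lognormal_noise(1, x), numeric(1))
    area <- conc * slope * rec * me * bias *
      grid$true_ion_fraction / grid$quant_fraction * eps

    # one jitter draw per sample x compound, shared by its transitions
    jkey <- paste(grid$sample_id, grid$compound_id)
    ujit <- stats::setNames(
      stats::rnorm(length(unique(jkey)), 0, params$rt_jitter_sd),
      unique(jkey)
    )
    rt <- unname(compound_rt[grid$compound_id] + ujit[jkey])
  })

  height <- area / (params$peak_sigma_min * sqrt(2 * pi))
  snr <- if (params$baseline_noise_sd > 0) {
    height / params$baseline_noise_sd
  } else {
    rep(Inf, length(height))
  }

  tibble::tibble(
    sample_id = grid$sample_id,
    transition_id = grid$transition_id,
    area = unname(area),
    rt = rt,
    snr = unname(snr)
  )
}
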