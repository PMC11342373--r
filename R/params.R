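#' Default forward-model parameters for the synthetic-batch generator
#'
#' Bundles the measurement-process parameters assumed by
#' [simulate_peak_table()]: detector response slopes, absolute recoveries of
#' the sample-preparation chain per compound and matrix category, per-category
#' ionization matrix effects, procedural-blank contamination levels,
#' endogenous background, multiplicative measurement noise, retention-time
#' jitter and the chromatographic peak geometry used to convert areas into
#' signal-to-noise ratios.
#'
#' Defaults emulate the measurement structure of a produce PFAS method:
#' absolute recoveries between 32 and 79% (bulb vegetables lowest), matrix
#' effects from 32% (bulb vegetables and leek) to 157% (leafy vegetables),
#' analyte-specific procedural-blank contamination of about 5 ng/kg for PFOA
#' and 0.5 ng/kg for PFNA, a 10% multiplicative noise CV, and an
#' internal-standard nominal level of 5 ng/kg-equivalent (50 uL of 1 ng/mL
#' added to 10 g of sample).
#'
#' @param panel A `pfas_panel`; parameters are generated for every compound
#'   in it.
#' @param noise_cv Multiplicative measurement noise, as a CV (unit-mean
#'   lognormal). Default 0.10.
#' @param rt_jitter_sd Gaussian retention-time jitter sd in minutes.
#' @param blank_level Named numeric vector of procedural-blank contamination
#'   (ng/kg) per analyte; analytes not named are 0.
#' @param analyte_bias Named multiplicative bias per analyte, applied to
#'   spiked and unknown samples but not to the MFS calibrants or blanks:
#'   it models a surrogate-internal-standard mismatch between the
#'   calibration matrix and the other matrices, which single-matrix
#'   calibration cannot correct. Analytes not named are unbiased.
#' @param analyte_cv Named per-analyte noise CV overriding `noise_cv`.
#' @param interference_spec Optional list(transition_id, rt_offset_min, area)
#'   describing a coeluting interference peak injected by
#'   [synthesize_traces()] on a single transition.
#' @return A `generation_params` list.
#' @examples
#' p <- default_generation_params(build_default_panel())
#' p$matrix_effect
#' @export
default_generation_params <- function(panel,
                                      noise_cv = 0.10,
                                      rt_jitter_sd = 0.01,
                                      blank_level = c(PFOA = 5, PFNA = 0.5),
                                      analyte_bias = NULL,
                                      analyte_cv = NULL,
                                      interference_spec = NULL) {
  compounds <- c(
    panel$analytes$analyte_id,
    panel$internal_standards$is_id,
    panel$injection_standards$id
  )
  slope <- stats::setNames(rep(200, length(compounds)), compounds)

  # per-category preparation recovery, modulated by chain length: long-chain
  # compounds adsorb to surfaces and recover worse
  base_rec <- c(leafy = 0.65, bulb_leek = 0.42, root = 0.60,
                fruit = 0.62, other = 0.58)
  chain_factor <- stats::setNames(rep(1, length(compounds)), compounds)
  long_chain <- c("PFDoDA", "PFTrDA", "PFTeDA", "PFDS", "PFOSA",
                  "13C2-PFDoDA", "11Cl-PF3OUdS")
  chain_factor[intersect(long_chain, compounds)] <- 0.78
  abs_recovery <- outer(chain_factor, base_rec)  # compounds x categories
  abs_recovery[] <- pmin(pmax(abs_recovery, 0.32), 0.79)

  matrix_effect <- c(leafy = 1.57, bulb_leek = 0.32, root = 0.90,
                     fruit = 1.05, other = 1.10)

  bl <- stats::setNames(rep(0, nrow(panel$analytes)), panel$analytes$analyte_id)
  bl[names(blank_level)] <- blank_level

  structure(
    list(
      response_slope = slope,
      abs_recovery = abs_recovery,
      matrix_effect = matrix_effect,
      blank_level = bl,
      endogenous = NULL,     # optional tibble(analyte_id, matrix_name, conc_ng_kg)
      noise_cv = noise_cv,
      analyte_cv = analyte_cv,
      analyte_bias = analyte_bias,
      rt_jitter_sd = rt_jitter_sd,
      is_nominal_ng_kg = 5,
      peak_sigma_min = 0.05,
      baseline_noise_sd = 20,
      interference_spec = interference_spec
    ),
    class = "generation_params"
  )
}

# unit-mean lognormal multipliers with coefficient of variation cv
lognormal_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log1p(cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}
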