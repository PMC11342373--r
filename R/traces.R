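#' Synthesize raw MRM chromatogram traces from a peak table
#'
#' Renders each (sample, transition) row of a peak table as a Gaussian
#' chromatographic peak of the tabulated area at the tabulated retention
#' time, on a flat baseline with white Gaussian noise, sampled on a regular
#' time grid centred on the compound's expected retention time. An optional
#' coeluting interference (e.g. a TDCA-like bile acid sharing the most
#' sensitive PFOS transition) is added as an independent Gaussian peak on a
#' single named transition at a fixed retention-time offset.
#'
#' @param peak_table Tibble (sample_id, transition_id, area, rt) as produced
#'   by [simulate_peak_table()].
#' @param panel A `pfas_panel` (provides expected retention times for the
#'   trace windows).
#' @param trace_params List with `sigma_min` (Gaussian peak sd, minutes),
#'   `dt_min` (sampling interval), `noise_sd` (baseline white-noise sd),
#'   `window_min` (half-width of the trace around the expected RT) and
#'   optionally `interference` = list(transition_id, rt_offset_min, area).
#' @param seed Integer seed for the baseline noise.
#' @return Long tibble (sample_id, transition_id, time_min, intensity).
#' @examples
#' panel <- build_default_panel()
#' pt <- tibble::tibble(sample_id = "s1",
#'                      transition_id = "PFOA_413>369", area = 50, rt = 4.5)
#' tr <- synthesize_traces(pt, panel, seed = 1)
#' @export
synthesize_traces <- function(peak_table, panel,
                              trace_params = default_trace_params(),
                              seed = 1L) {
  tp <- utils::modifyList(default_trace_params(), trace_params)
  if (tp$dt_min > tp$sigma_min) {
    stop("sampling interval dt_min exceeds peak sigma: peak would be undersampled")
  }

  rt_lookup <- transition_expected_rt(panel)
  exp_rt <- rt_lookup[peak_table$transition_id]
  if (anyNA(exp_rt)) {
    stop(
      "unknown transition ids in peak table: ",
      paste(unique(peak_table$transition_id[is.na(exp_rt)]), collapse = ", ")
    )
  }

  n_pts <- floor(tp$window_min / tp$dt_min)
  offsets <- seq(-n_pts, n_pts) * tp$dt_min

  withr::with_seed(seed, {
    traces <- purrr::pmap(
      list(peak_table$sample_id, peak_table$transition_id,
           peak_table$area, peak_table$rt, unname(exp_rt)),
      function(sid, tid, area, rt, rt0) {
        tgrid <- rt0 + offsets
        intensity <- area * stats::dnorm(tgrid, mean = rt, sd = tp$sigma_min)
        if (!is.null(tp$interference) && tid == tp$interference$transition_id) {
          intensity <- intensity + tp$interference$area *
            stats::dnorm(tgrid, mean = rt0 + tp$interference$rt_offset_min,
                         sd = tp$sigma_min)
        }
        if (tp$noise_sd > 0) {
          intensity <- intensity + stats::rnorm(length(tgrid), 0, tp$noise_sd)
        }
        tibble::tibble(sample_id = sid, transition_id = tid,
                       time_min = tgrid, intensity = intensity)
      }
    )
  })
  dplyr::bind_rows(traces)
}

#' Default chromatogram rendering parameters
#'
#' Gaussian peak sd 0.05 min (~7 s base width), 0.005 min sampling
#' (10 points per sd), half-window 0.5 min, noiseless baseline.
#' @export
default_trace_params <- function() {
  list(
    sigma_min = 0.05,
    dt_min = 0.005,
    noise_sd = 0,
    window_min = 0.5,
    interference = NULL
  )
}

# expected retention time per transition id
transition_expected_rt <- function(panel) {
  rt <- c(
    stats::setNames(panel$analytes$expected_rt, panel$analytes$analyte_id),
    stats::setNames(panel$internal_standards$expected_rt,
                    panel$internal_standards$is_id),
    stats::setNames(panel$injection_standards$expected_rt,
                    panel$injection_standards$id)
  )
  stats::setNames(
    unname(rt[panel$transitions$compound_id]),
    panel$transitions$transition_id
  )
}
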