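#' Detect and integrate one chromatographic peak
#'
#' Locates the apex of the largest peak inside a retention-time window on a
#' lightly smoothed copy of the trace (5-point moving average), estimates
#' the Gaussian width from the full width at half maximum, and integrates
#' the unsmoothed trace by the trapezoidal rule between apex +/- 4 sigma
#' (falling back to the nearest valleys when the half-height width cannot be
#' measured). A straight baseline interpolated between the bound intensities
#' is subtracted. Baseline noise is the sd of the trace in the signal-free
#' region outside apex +/- 5 sigma; a peak whose apex height is below 3x
#' that noise is reported as not found.
#'
#' The signal-to-noise ratio is apex height over baseline-noise sd; on a
#' noiseless trace it is `Inf`. A coeluting interference inside the
#' integration bounds is not deconvolved and contaminates the area — the
#' ion-ratio confirmation rules are the safety net for that case.
#'
#' @param trace Tibble with `time_min` and `intensity` for one transition.
#' @param expected_rt Centre of the search window (minutes).
#' @param rt_window Half-width of the search window (minutes, > 0).
#' @param peak_params List: `smooth_pts` (moving-average width, default 5),
#'   `min_snr` (detection threshold, default 3).
#' @return One-row tibble (rt_apex, area, height, baseline_noise_sd, snr,
#'   found).
#' @examples
#' t <- seq(4, 5, by = 0.005)
#' tr <- tibble::tibble(time_min = t,
#'                      intensity = 10 * dnorm(t, 4.5, 0.05))
#' process_trace(tr, expected_rt = 4.5, rt_window = 0.3)
#' @export
process_trace <- function(trace, expected_rt, rt_window = 0.3,
                          peak_params = list()) {
  pp <- utils::modifyList(list(smooth_pts = 5, min_snr = 3), peak_params)
  stopifnot(rt_window > 0)
  t <- trace$time_min
  y <- trace$intensity
  if (expected_rt - rt_window < min(t) || expected_rt + rt_window > max(t)) {
    stop("search window extends outside the trace extent")
  }

  ys <- moving_average(y, pp$smooth_pts)
  in_win <- which(t >= expected_rt - rt_window & t <= expected_rt + rt_window)
  apex_i <- in_win[which.max(ys[in_win])]
  rt_apex <- t[apex_i]

  sigma <- fwhm_sigma(t, ys, apex_i)
  if (is.na(sigma)) {
    bounds <- valley_bounds(ys, apex_i)
  } else {
    lo_t <- rt_apex - 4 * sigma
    hi_t <- rt_apex + 4 * sigma
    bounds <- c(max(1, which.min(abs(t - lo_t))), which.min(abs(t - hi_t)))
  }
  lo <- bounds[1]; hi <- bounds[2]

  # straight baseline between the integration bounds, on the raw trace
  base <- y[lo] + (y[hi] - y[lo]) * (t[lo:hi] - t[lo]) / (t[hi] - t[lo])
  area <- pracma::trapz(t[lo:hi], y[lo:hi] - base)
  height <- y[apex_i] - stats::approx(t[c(lo, hi)], y[c(lo, hi)],
                                      xout = rt_apex)$y

  noise_sigma <- if (is.na(sigma)) (t[hi] - t[lo]) / 8 else sigma
  free <- which(t < rt_apex - 5 * noise_sigma | t > rt_apex + 5 * noise_sigma)
  baseline_noise_sd <- if (length(free) >= 4) {
    stats::sd(y[free] - stats::median(y[free]))
  } else {
    NA_real_
  }

  snr <- if (is.na(baseline_noise_sd)) {
    NA_real_
  } else if (baseline_noise_sd == 0) {
    Inf
  } else {
    height / baseline_noise_sd
  }

  found <- is.na(baseline_noise_sd) || baseline_noise_sd == 0 ||
    height >= pp$min_snr * baseline_noise_sd
  if (!found || height <= 0) {
    if (height <= 0) found <- FALSE
    if (!found) { area <- 0; height <- 0 }
  }

  tibble::tibble(
    rt_apex = rt_apex, area = area, height = height,
    baseline_noise_sd = baseline_noise_sd, snr = snr, found = found
  )
}

#' Integrate every trace in a long-format chromatogram table
#'
#' Applies [process_trace()] to each (sample_id, transition_id) group,
#' searching around the panel's expected retention time for that transition,
#' and returns a peak table in the interchange schema.
#'
#' @param traces Long tibble (sample_id, transition_id, time_min, intensity).
#' @param panel A `pfas_panel`.
#' @inheritParams process_trace
#' @return Tibble (sample_id, transition_id, area, rt, snr, found).
#' @export
process_traces <- function(traces, panel, rt_window = 0.3, peak_params = list()) {
  rt_lookup <- transition_expected_rt(panel)
  traces |>
    dplyr::group_by(.data$sample_id, .data$transition_id) |>
    dplyr::group_modify(function(df, key) {
      res <- process_trace(df, rt_lookup[[key$transition_id]],
                           rt_window, peak_params)
      tibble::tibble(area = res$area, rt = res$rt_apex, snr = res$snr,
                     found = res$found)
    }) |>
    dplyr::ungroup()
}

#' Relative retention time
#'
#' Retention time of the analyte divided by the retention time of its
#' internal standard; the identity-confirmation rule allows at most 1%
#' deviation from the reference relative retention time.
#'
#' @param rt_analyte Analyte retention time (minutes).
#' @param rt_is Internal-standard retention time (minutes, > 0).
#' @return Dimensionless ratio.
#' @examples
#' compute_rrt(5.05, 5.00)
#' @export
compute_rrt <- function(rt_analyte, rt_is) {
  if (any(rt_is <= 0)) stop("internal-standard retention time must be positive")
  rt_analyte / rt_is
}

moving_average <- function(y, k) {
  if (k <= 1) return(y)
  half <- floor(k / 2)
  n <- length(y)
  cs <- cumsum(c(0, y))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# Gaussian sd from full width at half maximum around an apex; NA when the
# half-height crossings are not bracketed inside the trace
fwhm_sigma <- function(t, ys, apex_i) {
  floor_y <- min(ys)
  half <- floor_y + (ys[apex_i] - floor_y) / 2
  left <- apex_i
  while (left > 1 && ys[left] > half) left <- left - 1
  right <- apex_i
  n <- length(ys)
  while (right < n && ys[right] > half) right <- right + 1
  if (ys[left] > half || ys[right] > half) return(NA_real_)
  tl <- stats::approx(ys[c(left, left + 1)], t[c(left, left + 1)], xout = half)$y
  tr <- stats::approx(ys[c(right - 1, right)], t[c(right - 1, right)], xout = half)$y
  (tr - tl) / (2 * sqrt(2 * log(2)))
}

# nearest local minima on either side of the apex (fallback bounds)
valley_bounds <- function(ys, apex_i) {
  n <- length(ys)
  left <- apex_i
  while (left > 1 && ys[left - 1] <= ys[left]) left <- left - 1
  right <- apex_i
  while (right < n && ys[right + 1] <= ys[right]) right <- right + 1
  c(left, right)
}
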