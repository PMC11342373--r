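# shared fixtures: one panel, small noise-free batches
fixture_panel <- build_default_panel()

noise_free_params <- function(panel = fixture_panel, ...) {
  default_generation_params(panel, noise_cv = 0, rt_jitter_sd = 0, ...)
}

# one quantified noise-free fruit batch reused across tests
fixture_batch <- local({
  d <- design_validation_batch("fruit", seed = 11)
  pt <- simulate_peak_table(d, noise_free_params(), fixture_panel)
  q <- quantify_batch(pt, fixture_panel, d$samples)
  list(design = d, peaks = pt, quant = q)
})

# a single synthetic Gaussian trace
gaussian_trace <- function(area = 1, rt = 5, sigma = 0.05, dt = 0.005,
                           window = 0.5, noise_sd = 0, seed = 1) {
  t <- seq(rt - window, rt + window, by = dt)
  y <- area * dnorm(t, rt, sigma)
  if (noise_sd > 0) {
    y <- y + withr::with_seed(seed, rnorm(length(t), 0, noise_sd))
  }
  tibble::tibble(time_min = t, intensity = y)
}

# brute-force weighted least squares through the normal equations
wls_oracle <- function(x, y, w) {
  X <- cbind(1, x)
  A <- t(X) %*% (w * X)
  b <- t(X) %*% (w * y)
  unname(solve(A, b)[, 1])
}
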