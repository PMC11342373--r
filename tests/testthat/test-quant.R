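test_that("response ratio is analyte over internal-standard area", {
  expect_equal(response_ratio(0.50, 1.00), 0.50)
  expect_equal(response_ratio(0.0, 1.0), 0.0)
  expect_equal(response_ratio(3.3, 1.1), 3.0)
  expect_warning(r <- response_ratio(1, 0), "not positive")
  expect_true(is.na(r))
})

test_that("blank averaging and subtraction behave as documented", {
  b <- average_blank_response(tibble::tibble(
    analyte_id = "PFOA", response = c(0.010, 0.014)
  ))
  expect_equal(b$blank_response, 0.012)
  expect_warning(
    s <- average_blank_response(tibble::tibble(analyte_id = "PFOA",
                                               response = 0.02)),
    "single"
  )
  expect_equal(s$blank_response, 0.02)
  expect_warning(average_blank_response(tibble::tibble(analyte_id = character(),
                                                       response = numeric())),
                 "skipped")
  expect_equal(blank_correct(0.105, 0.012), 0.093)
  expect_equal(blank_correct(0.010, 0.012), -0.002)  # retained, not clipped
  expect_equal(blank_correct(0.4, 0), 0.4)
})

test_that("an exact line is recovered to machine precision", {
  lv <- mfs_levels_default()
  cal <- tibble::tibble(conc = lv, response = 0.01 * lv)
  m <- fit_mfs_calibration(cal, segment = c(0, 2000))
  expect_equal(m$slope, 0.01, tolerance = 1e-12)
  expect_equal(m$intercept, 0, tolerance = 1e-12)
})

test_that("weighted fit matches the normal-equations oracle to 1e-10", {
  set.seed(31)
  x <- c(0, 0.5, 1, 2.5, 5, 10, 50, 100)
  y <- 0.004 * x + 0.001 + rnorm(length(x), 0, 0.002)
  m <- fit_mfs_calibration(tibble::tibble(conc = x, response = y), c(0, 100))
  w <- ifelse(x > 0, 1 / x, 1)
  oracle <- wls_oracle(x, y, w)
  expect_equal(m$intercept, oracle[1], tolerance = 1e-10)
  expect_equal(m$slope, oracle[2], tolerance = 1e-10)
})

test_that("duplicate levels both enter the fit", {
  x <- c(0, 1, 5, 10, 50, 50)
  y <- c(0, 0.01, 0.05, 0.10, 0.48, 0.52)
  m <- fit_mfs_calibration(tibble::tibble(conc = x, response = y), c(0, 100))
  w <- ifelse(x > 0, 1 / x, 1)
  oracle <- wls_oracle(x, y, w)
  expect_equal(m$slope, oracle[2], tolerance = 1e-10)
  expect_equal(m$n_points, 6)
})

test_that("degenerate calibrations are rejected", {
  expect_error(
    fit_mfs_calibration(tibble::tibble(conc = c(0, 1, 5), response = 0:2 / 100),
                        c(0, 100)),
    ">= 5"
  )
  expect_error(
    fit_mfs_calibration(tibble::tibble(conc = c(0, 1, 5, 10, 50),
                                       response = rep(0.3, 5)),
                        c(0, 100)),
    "degenerate"
  )
})

test_that("segment selection brackets the preliminary concentration", {
  expect_equal(select_segment(5)$segment, c(0, 100))
  expect_equal(select_segment(600)$segment, c(50, 2000))
  s <- select_segment(3000)
  expect_equal(s$segment, c(50, 2000))
  expect_true(s$extrapolated)
})

test_that("quantify inverts the model and preserves negatives", {
  m <- structure(list(slope = 0.02, intercept = 0.001),
                 class = "mfs_calibration")
  expect_equal(quantify(0.101, m), 5.0)
  expect_equal(quantify(0.001, m), 0.0)
  expect_lt(quantify(0.0, m), 0)
  bad <- structure(list(slope = 0, intercept = 0), class = "mfs_calibration")
  expect_error(quantify(1, bad), "positive")
})

test_that("noise-free batches round-trip every spiked level exactly", {
  res <- fixture_batch$quant$results
  spiked <- dplyr::filter(res, role %in% c("spiked", "mfs_calibrant"))
  expect_true(all(abs(spiked$conc - spiked$spike_level_ng_kg) < 1e-6))
})

test_that("scaling analyte and IS areas together leaves concentrations unchanged", {
  d <- fixture_batch$design
  pt <- fixture_batch$peaks
  # double every area (same factor for analyte and IS): recovery/matrix-effect
  # robustness of the isotope-dilution ratio
  pt2 <- dplyr::mutate(pt, area = area * 2)
  q2 <- quantify_batch(pt2, fixture_panel, d$samples)
  expect_equal(q2$results$conc, fixture_batch$quant$results$conc,
               tolerance = 1e-10)
})

test_that("a constant added blank response cancels exactly", {
  d <- fixture_batch$design
  pt <- fixture_batch$peaks
  # add a constant response offset to every sample including the blanks, in
  # response space: area += c * is_area for each analyte
  panel <- fixture_panel
  is_of <- setNames(panel$analytes$is_id, panel$analytes$analyte_id)
  tr2cmp <- setNames(panel$transitions$compound_id, panel$transitions$transition_id)
  is_quant_tr <- panel$transitions |>
    dplyr::filter(compound_id %in% panel$internal_standards$is_id) |>
    (\(x) setNames(x$transition_id, x$compound_id))()
  is_area <- pt |>
    dplyr::filter(transition_id %in% is_quant_tr) |>
    dplyr::mutate(compound = tr2cmp[transition_id]) |>
    dplyr::select(sample_id, compound, is_area = area)
  pt2 <- pt |>
    dplyr::mutate(compound = tr2cmp[transition_id],
                  is_id = is_of[compound]) |>
    dplyr::left_join(is_area, by = c("sample_id", is_id = "compound")) |>
    dplyr::mutate(
      area = ifelse(!is.na(is_area), area + 0.05 * is_area, area)
    ) |>
    dplyr::select(sample_id, transition_id, area, rt, snr)
  q2 <- quantify_batch(pt2, fixture_panel, d$samples)
  expect_equal(q2$results$conc, fixture_batch$quant$results$conc,
               tolerance = 1e-8)
})

test_that("mean quantified/spiked ratio stays near 1 under 5% noise", {
  panel <- fixture_panel
  params <- default_generation_params(panel, noise_cv = 0.05)
  ratios <- purrr::map_dbl(1:5, function(i) {
    d <- design_validation_batch(pfas_categories()[i], seed = 100 + i)
    pt <- simulate_peak_table(d, params, panel)
    q <- quantify_batch(pt, panel, d$samples)
    # analytes without procedural-blank contamination: the ratio then
    # reflects calibration + noise alone
    sp <- dplyr::filter(q$results, role == "spiked",
                        analyte_id %in% c("PFHxS", "PFOS", "PFHxA"))
    mean(sp$conc / sp$spike_level_ng_kg)
  })
  # 30 spiked samples per category x 3 analytes
  expect_true(all(ratios > 0.97 & ratios < 1.03))
})

test_that("tidy and glance expose the calibration parameters", {
  m <- fixture_batch$quant$models$PFOA$low
  td <- generics::tidy(m)
  expect_equal(td$estimate[td$term == "conc"], m$slope)
  gl <- generics::glance(m)
  expect_equal(gl$analyte_id, "PFOA")
  expect_equal(gl$n_points, m$n_points)
  expect_s3_class(ggplot2::autoplot(m), "ggplot")
})
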