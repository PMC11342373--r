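test_that("ion ratio and relative deviation are the definitional ratios", {
  expect_equal(ion_ratio(0.30, 1.00), 0.30)
  expect_equal(ion_ratio(0, 1.0), 0.0)
  expect_equal(ion_ratio(1.2, 0.6), 2.0)
  expect_true(is.na(ion_ratio(0.3, 0)))
  expect_equal(relative_deviation(0.39, 0.30), 30.0)
  expect_equal(relative_deviation(0.30, 0.30), 0.0)
  expect_equal(relative_deviation(1.01, 1.00), 1.0)
  expect_error(relative_deviation(1, 0), "positive")
})

test_that("confirmation bounds are inclusive at 30% and 1%", {
  vi <- tibble::tibble(
    ion_ratio = c(0.39, 0.301 * 1.3, 0.39),
    rrt = c(1.01, 1.0, 1.0),
    ref_ion_ratio = 0.30,
    ref_rrt = 1.0
  )
  vi$ion_ratio[2] <- 0.30 * 1.301   # 30.1% deviation
  out <- check_confirmation(vi)
  expect_true(out$confirmed[1])                 # exactly 30% and 1%
  expect_false(out$confirmed[2])
  expect_match(out$reasons[2], "ion-ratio")
  expect_true(out$confirmed[3])
  # rrt boundary + epsilon
  out2 <- check_confirmation(tibble::tibble(
    ion_ratio = 0.30, rrt = 1.0101, ref_ion_ratio = 0.30, ref_rrt = 1.0
  ))
  expect_false(out2$confirmed)
  expect_match(out2$reasons, "rrt")
})

test_that("scanning deviations finds 30% and 1% as the largest passing", {
  devs <- seq(0, 40, by = 0.05)
  out <- check_confirmation(tibble::tibble(
    ion_ratio = 0.30 * (1 + devs / 100), rrt = 1, ref_ion_ratio = 0.30,
    ref_rrt = 1
  ))
  expect_equal(max(devs[out$confirmed]), 30)
  rdevs <- seq(0, 2, by = 0.005)
  out2 <- check_confirmation(tibble::tibble(
    ion_ratio = 0.30, rrt = 1 + rdevs / 100, ref_ion_ratio = 0.30, ref_rrt = 1
  ))
  expect_equal(max(rdevs[out2$confirmed]), 1)
})

test_that("verdicts are invariant to symmetric area scaling", {
  base <- tibble::tibble(area_quant = 100, ion_ratio = 0.35, rrt = 1.002,
                         ref_ion_ratio = 0.30, ref_rrt = 1.0)
  scaled <- dplyr::mutate(base, area_quant = area_quant * 7)
  expect_equal(check_confirmation(base)$confirmed,
               check_confirmation(scaled)$confirmed)
})

test_that("the verdict is confirmed on exactly one contiguous ratio interval", {
  ratios <- seq(0.01, 1.2, by = 0.01)
  out <- check_confirmation(tibble::tibble(
    ion_ratio = ratios, rrt = 1, ref_ion_ratio = 0.30, ref_rrt = 1
  ))
  runs <- rle(out$confirmed)
  expect_equal(sum(runs$values), 1)
})

test_that("missing references yield a not-assessable verdict", {
  out <- check_confirmation(tibble::tibble(
    ion_ratio = 0.3, rrt = 1, ref_ion_ratio = NA_real_, ref_rrt = 1
  ))
  expect_false(out$confirmed)
  expect_match(out$reasons, "not-assessable")
})

test_that("noise-free calibrants confirm against their own references", {
  conf <- confirm_batch(fixture_batch$quant)
  calib <- dplyr::filter(conf, role == "mfs_calibrant", spike_level_ng_kg > 0)
  expect_true(all(calib$confirmed))
  # PFPeA confirms through its pseudo transition, with the caveat flag
  pfpea <- dplyr::filter(calib, analyte_id == "PFPeA")
  expect_true(all(pfpea$caveat == "pseudo-ratio"))
})

test_that("a coeluting interference on the PFOS qualifier breaks confirmation", {
  d <- design_validation_batch("fruit", seed = 33)
  params <- noise_free_params()
  pt <- simulate_peak_table(d, params, fixture_panel)
  # render PFOS traces for spiked samples with a TDCA-like interferent on the
  # 499>80 qualifier, coeluting closely enough to contaminate its area
  pfos_tr <- dplyr::filter(fixture_panel$transitions,
                           compound_id == "PFOS")$transition_id
  spiked_ids <- d$samples$sample_id[d$samples$role == "spiked" &
                                      d$samples$spike_level_ng_kg == 50]
  sub <- dplyr::filter(pt, transition_id %in% pfos_tr,
                       sample_id %in% spiked_ids)
  spec <- list(transition_id = "PFOS_499>80", rt_offset_min = 0.05,
               area = max(sub$area) * 3)
  traces <- synthesize_traces(sub, fixture_panel,
                              trace_params = list(noise_sd = 0,
                                                  interference = spec),
                              seed = 2)
  integrated <- process_traces(traces, fixture_panel) |>
    dplyr::mutate(snr = Inf)
  # splice the contaminated PFOS areas back into the batch
  pt2 <- pt |>
    dplyr::rows_update(
      dplyr::select(integrated, sample_id, transition_id, area, rt, snr),
      by = c("sample_id", "transition_id")
    )
  q <- quantify_batch(pt2, fixture_panel, d$samples)
  conf <- confirm_batch(q)
  hit <- dplyr::filter(conf, analyte_id == "PFOS", sample_id %in% spiked_ids)
  # direct-ratio oracle: qualifier inflated ~3x the quantifier-implied ratio
  expect_true(all(hit$ion_ratio_dev > 30))
  expect_true(all(!hit$confirmed))
  expect_true(all(grepl("ion-ratio", hit$reasons)))
  # quantification on 499>99 is untouched
  expect_equal(dplyr::filter(q$results, analyte_id == "PFOS",
                             sample_id %in% spiked_ids)$conc,
               rep(50, length(spiked_ids)), tolerance = 0.01)
})
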