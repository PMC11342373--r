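test_that("the S/N-based LOQ is the lowest qualifying calibration level", {
  expect_equal(
    loq_snr_strategy(tibble::tibble(conc = c(0.5, 1), snr = c(8, 20)))$loq,
    0.5
  )
  expect_equal(
    loq_snr_strategy(tibble::tibble(conc = c(0.5, 1), snr = c(4, 7)))$loq,
    1.0
  )
  out <- loq_snr_strategy(tibble::tibble(conc = c(0.5, 1), snr = c(2, 3)))
  expect_true(is.na(out$loq))
  expect_equal(out$flag, "undeterminable")
  # the zero level never qualifies
  expect_equal(
    loq_snr_strategy(tibble::tibble(conc = c(0, 0.5), snr = c(50, 8)))$loq,
    0.5
  )
})

test_that("the blank-based LOQ applies the 3.3 factor", {
  expect_equal(loq_blank_strategy(5), 16.5)
  expect_equal(loq_blank_strategy(0.5), 1.65)
  expect_equal(loq_blank_strategy(1.0), 3.3)
  expect_error(loq_blank_strategy(0), "positive")
})

test_that("raw LOQs snap up to the calibration grid", {
  expect_equal(snap_to_level(16.5)$loq, 25)    # 5 ng/kg blank -> 25
  expect_equal(snap_to_level(1.65)$loq, 2.5)   # 0.5 ng/kg blank -> 2.5
  expect_equal(snap_to_level(0.5)$loq, 0.5)    # already on grid
  out <- snap_to_level(5000)
  expect_equal(out$loq, 2000)
  expect_equal(out$flag, "above-calibration")
})

test_that("the LOC is the lowest confirming level, floored at the LOQ", {
  expect_equal(
    determine_loc(tibble::tibble(conc = c(0.5, 1, 2.5),
                                 confirmed = c(FALSE, FALSE, TRUE)),
                  loq = 0.5)$loc,
    2.5
  )
  expect_equal(
    determine_loc(tibble::tibble(conc = c(0.5, 1, 2.5),
                                 confirmed = c(TRUE, TRUE, TRUE)),
                  loq = 2.5)$loc,
    2.5
  )
  out <- determine_loc(tibble::tibble(conc = 0.5, confirmed = FALSE), 0.5)
  expect_true(is.na(out$loc))
  expect_equal(out$flag, "undeterminable")
})

test_that("the blank-contribution rule flags strictly above 30%", {
  expect_true(blank_contribution_check(3, 10))    # exactly 30% passes
  expect_false(blank_contribution_check(4, 10))
  expect_true(blank_contribution_check(0, 7))
  ratios <- seq(0, 0.6, by = 0.01)
  pass <- blank_contribution_check(ratios * 10, rep(10, length(ratios)))
  expect_equal(max(ratios[pass]), 0.30)
})

test_that("LOQs are reconciled against validation performance", {
  vr <- tibble::tibble(spike_level = c(2.5, 50, 500),
                       recovery_mean = c(150, 103, 101),
                       rsd_rl = c(40, 8, 5))
  out <- assess_loq_against_validation(0.5, vr)
  expect_equal(out$loq, 50)
  expect_equal(out$flag, "raised")
  ok <- tibble::tibble(spike_level = c(2.5, 50), recovery_mean = c(95, 103),
                       rsd_rl = c(12, 8))
  expect_equal(assess_loq_against_validation(0.5, ok)$flag, "")
  none <- assess_loq_against_validation(0.5, vr[0, ])
  expect_equal(none$flag, "unassessed")
})

test_that("batch limits use the right strategy per analyte and satisfy LOC >= LOQ", {
  conf <- confirm_batch(fixture_batch$quant)
  lim <- determine_limits(conf)
  pfoa <- dplyr::filter(lim, analyte_id == "PFOA")
  expect_equal(pfoa$loq_strategy, "blank_based")
  expect_equal(pfoa$blank_conc, 5, tolerance = 1e-6)
  expect_equal(pfoa$loq_raw, 16.5, tolerance = 1e-6)
  expect_equal(pfoa$loq, 25)
  pfna <- dplyr::filter(lim, analyte_id == "PFNA")
  expect_equal(pfna$loq_strategy, "blank_based")
  expect_equal(pfna$loq, 2.5)
  clean <- dplyr::filter(lim, !analyte_id %in% c("PFOA", "PFNA"))
  expect_true(all(clean$loq_strategy == "snr_based"))
  expect_true(all(lim$loc >= lim$loq, na.rm = TRUE))
  expect_true(all(lim$loq %in% mfs_levels_default(), na.rm = TRUE))
})

test_that("a larger blank never lowers the blank-based LOQ", {
  blanks <- c(0.2, 0.5, 1, 2, 5, 8, 20)
  loqs <- purrr::map_dbl(blanks,
                         ~ snap_to_level(loq_blank_strategy(.x))$loq)
  expect_true(all(diff(loqs) >= 0))
})
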