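test_that("apparent recovery follows its definition", {
  expect_equal(apparent_recovery(51.5, 50, 0), 103.0)
  expect_equal(apparent_recovery(55, 50, 5), 100.0)
  expect_equal(apparent_recovery(0, 50, 0), 0.0)
  expect_error(apparent_recovery(1, 0), "positive")
})

test_that("rsd is the n-1 standard deviation over the absolute mean", {
  expect_equal(rsd(c(90, 100, 110)), 10.0)
  expect_equal(rsd(c(5, 5, 5)), 0.0)
  expect_error(rsd(5), "at least 2")
  expect_error(rsd(c(-1, 1)), "zero mean")
  # 30 lognormal draws at CV 10%: estimate lands in a plausible band and
  # matches a direct recomputation
  x <- withr::with_seed(17, rlnorm(30, -0.005, sqrt(log1p(0.01))))
  expect_gt(rsd(x), 6); expect_lt(rsd(x), 14)
  expect_equal(rsd(x), sd(x) / mean(x) * 100)
})

test_that("noise-free aggregation is exactly degenerate", {
  conf <- confirm_batch(fixture_batch$quant)
  summ <- aggregate_validation(conf)
  expect_true(all(abs(summ$recovery_mean - 100) < 1e-8))
  expect_true(all(summ$rsd_rl < 1e-6))
  expect_true(all(summ$rsd_r < 1e-6))
  expect_true(all(summ$n_confirmed == summ$n_samples))
})

test_that("within-category RSD is below across-category RSD under category bias", {
  # constructed data: categories differ by a level shift
  rec <- tidyr::expand_grid(cat = c("a", "b", "c"), i = 1:6) |>
    dplyr::mutate(recovery = 100 + 10 * (match(cat, c("a", "b", "c")) - 2) +
                    c(-1, 1)[1 + i %% 2])
  within <- rec |>
    dplyr::summarise(r = rsd(recovery), .by = cat) |>
    dplyr::pull(r) |>
    mean()
  across <- rsd(rec$recovery)
  expect_lt(within, across)
})

test_that("classification applies inclusive monitoring criteria per level", {
  s <- tibble::tibble(
    analyte_id = c("A", "A", "B", "B", "C"),
    spike_level = c(50, 500, 50, 500, 50),
    recovery_mean = c(103, 99, 146, 139, 135),
    rsd_rl = c(8, 7, 44, 57, 25)
  )
  v <- classify(s)
  expect_equal(v$verdict[v$analyte_id == "A"], "quan")
  expect_equal(v$verdict[v$analyte_id == "B"], "qual")
  expect_equal(v$verdict[v$analyte_id == "C"], "quan")  # exactly 135 / 25
  # perturbing one level outside the band flips the verdict
  s2 <- s
  s2$recovery_mean[2] <- 64.9
  expect_equal(classify(s2)$verdict[1], "qual")
})

test_that("the stability ANOVA matches hand-computed sums of squares", {
  g <- list(a = c(4.1, 5.2, 6.3, 5.5), b = c(6.8, 7.9, 6.2, 7.1),
            c = c(5.0, 4.2, 5.8, 4.9))
  res <- anova_stability(g)
  # brute-force one-way ANOVA
  all_v <- unlist(g)
  gm <- mean(all_v)
  ssb <- sum(vapply(g, function(x) length(x) * (mean(x) - gm)^2, 0))
  ssw <- sum(vapply(g, function(x) sum((x - mean(x))^2), 0))
  f_oracle <- (ssb / (length(g) - 1)) / (ssw / (length(all_v) - length(g)))
  expect_equal(res$f_statistic, f_oracle, tolerance = 1e-10)
  expect_equal(res$p_value,
               pf(f_oracle, length(g) - 1, length(all_v) - length(g),
                  lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("ANOVA degenerate and null cases behave", {
  res <- anova_stability(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(res$f_statistic, 0)
  expect_equal(res$p_value, 1)
  # equal means, unequal spreads: mean-only sensitivity
  res2 <- anova_stability(list(a = c(9, 10, 11), b = c(5, 10, 15)))
  expect_lt(res2$f_statistic, 0.01)
  expect_error(anova_stability(list(a = 1, b = c(1, 2))), ">= 2")
  expect_s3_class(generics::glance(res), "tbl_df")
})

test_that("matrix effect and absolute recovery are the documented ratios", {
  expect_equal(matrix_effect(0.32, 1.00), 32.0)
  expect_equal(matrix_effect(1.0, 1.0), 100.0)
  expect_equal(matrix_effect(1.57, 1.00), 157.0)
  expect_error(matrix_effect(1, 0), "positive")
  expect_equal(absolute_recovery(0.41, 1.00), 41.0)
  expect_equal(absolute_recovery(1, 1), 100.0)
  expect_error(absolute_recovery(1, 0), "positive")
})

test_that("simulated injection standards recover the configured matrix effect and recovery", {
  d <- fixture_batch$design
  pt <- fixture_batch$peaks
  panel <- fixture_panel
  params <- noise_free_params()
  inj_tr <- panel$transitions |>
    dplyr::filter(compound_id %in% panel$injection_standards$id)
  samples <- d$samples
  inj <- pt |>
    dplyr::filter(transition_id %in% inj_tr$transition_id) |>
    dplyr::inner_join(samples[, c("sample_id", "role")], by = "sample_id")
  a_matrix <- mean(inj$area[inj$role == "spiked"])
  a_blank <- mean(inj$area[inj$role == "procedural_blank"])
  expect_equal(matrix_effect(a_matrix, a_blank),
               100 * params$matrix_effect[["fruit"]], tolerance = 1e-9)

  # absolute recovery round-trip for PFOA via IS / injection-standard ratio
  is_tr <- panel$transitions |>
    dplyr::filter(compound_id == "13C4-PFOA")
  inj_pfoa <- dplyr::filter(inj_tr, compound_id == "13C8-PFOA")
  sid <- samples$sample_id[samples$role == "spiked"][1]
  r_sample <- pt$area[pt$sample_id == sid &
                        pt$transition_id == is_tr$transition_id] /
    pt$area[pt$sample_id == sid & pt$transition_id == inj_pfoa$transition_id]
  r_ref <- params$response_slope[["13C4-PFOA"]] /
    params$response_slope[["13C8-PFOA"]] *
    is_tr$true_ion_fraction / inj_pfoa$true_ion_fraction
  expect_equal(absolute_recovery(r_sample, r_ref),
               100 * params$abs_recovery["13C4-PFOA", "fruit"],
               tolerance = 1e-9)
})

test_that("estimated reproducibility tracks the injected noise CV", {
  panel <- fixture_panel
  cvs <- c(0.02, 0.05, 0.10, 0.20)
  est <- purrr::map_dbl(cvs, function(cv) {
    params <- default_generation_params(panel, noise_cv = cv,
                                        blank_level = c(PFOA = 0))
    d <- design_validation_batch("fruit", seed = round(1000 * cv))
    pt <- simulate_peak_table(d, params, panel)
    q <- quantify_batch(pt, panel, d$samples)
    conf <- confirm_batch(q)
    summ <- aggregate_validation(conf)
    mean(summ$rsd_rl[summ$analyte_id == "PFOA"])
  })
  # response noise compounds analyte and IS draws: expect monotone increase
  expect_equal(cor(est, cvs, method = "kendall"), 1)
})
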