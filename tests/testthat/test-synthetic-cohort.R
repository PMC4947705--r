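test_that("sampling schedule follows the trial grid and truncates at PFS", {
  long <- sampling_schedule(400, progressed = TRUE)
  expect_equal(nrow(long), 10)
  expect_equal(long$time_days[10], 400)
  expect_equal(long$visit_label[10], "progression")
  expect_true(long$is_progression_sample[10])

  short <- sampling_schedule(150, progressed = TRUE)
  expect_equal(nrow(short), 7)
  expect_equal(short$time_days, c(-14, -1, 0, 21, 105, 126, 150))

  censored <- sampling_schedule(150, progressed = FALSE)
  expect_equal(nrow(censored), 6)
  expect_false(any(censored$is_progression_sample))

  expect_error(sampling_schedule(0), "positive")
  # never more than 10 visits, truncation respects PFS
  for (pfs in c(5, 63, 127, 366, 1200)) {
    sc <- sampling_schedule(pfs, progressed = TRUE)
    expect_lte(nrow(sc), 10)
    expect_true(all(sc$time_days <= pfs))
  }
})

test_that("noiseless trajectory generation is exact piecewise arithmetic", {
  flat <- piecewise_params(log(100), 0, 0, 5)
  expect_equal(generate_patient_trajectory(flat, c(-14, 0, 30, 300), 0),
               rep(100, 4))
  p <- piecewise_params(0, -0.2, 0.1, 5)
  expect_equal(log(generate_patient_trajectory(p, 7 * 30, 0)), -0.8)
  noisy <- generate_patient_trajectory(p, c(0, 30, 60), 0.3, seed = 9)
  expect_identical(noisy, generate_patient_trajectory(p, c(0, 30, 60), 0.3, seed = 9))
})

test_that("cohort generation honours counts, schedule and the seed contract", {
  co <- quick_cohort(n = 20, pfs = 400, seed = 1,
                     spec = point_spec(noise_sd = 0.2))
  expect_equal(nrow(co$samples), 200)  # 10 visits x 20 patients x 1 biomarker
  expect_identical(co$samples,
                   quick_cohort(n = 20, pfs = 400, seed = 1,
                                spec = point_spec(noise_sd = 0.2))$samples)
  expect_false(identical(co$samples,
                         quick_cohort(n = 20, pfs = 400, seed = 2,
                                      spec = point_spec(noise_sd = 0.2))$samples))
  # pre-treatment and progression visits survive missingness
  com <- quick_cohort(n = 30, pfs = 400, seed = 3, missing_rate = 0.5)
  per <- dplyr::count(com$samples[com$samples$time_days < 0, ], patient_id)
  expect_true(all(per$n == 2))
  expect_equal(sum(com$samples$is_progression_sample), 30)
  expect_lt(nrow(com$samples), 300)
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(n_standard = 0), ">= 1")
  expect_error(cohort_config(missing_rate = 1), "missing_rate")
  expect_error(cohort_config(biomarkers = list()), "at least one")
  expect_error(biomarker_spec("A", 0, -1, 0, 0, 0.1), ">= 0")
  expect_error(biomarker_spec("A", 0, 1, 0, 0, 0.1,
                              inflection_fraction_mean = 1.2), "(0, 1)")
})

test_that("shared latent factors induce the loading-implied correlation", {
  lam <- 0.9
  specs <- lapply(c("A", "B"), function(nm) biomarker_spec(
    nm, baseline_log_mean = 1, baseline_log_sd = 0,
    slope_before_mean = 0, slope_after_mean = 0, slope_sd = 0,
    inflection_fraction_mean = 0.5, inflection_fraction_sd = 0,
    noise_sd = 0.3, correlation_block = "blk", factor_loading = lam))
  co <- generate_cohort(cohort_config(
    n_standard = 250, n_experimental = 250, biomarkers = specs,
    pfs_distribution = list(name = "fixed", days = 400),
    censor_rate = 0, missing_rate = 0, seed = 11))
  wide <- tidyr::pivot_wider(
    co$samples[, c("patient_id", "time_days", "biomarker", "concentration")],
    names_from = "biomarker", values_from = "concentration")
  r <- cor(log(wide$A), log(wide$B))
  expect_equal(r, lam^2, tolerance = 0.05 / lam^2)
  expect_equal(nrow(wide), 5000)
})

test_that("pre-treatment log levels converge to the configured baseline", {
  spec <- biomarker_spec("A", baseline_log_mean = 2.5, baseline_log_sd = 0.4,
                         slope_before_mean = -1, slope_after_mean = 0.5,
                         slope_sd = 0.3, noise_sd = 0.2)
  co <- generate_cohort(cohort_config(
    n_standard = 150, n_experimental = 150, biomarkers = list(spec),
    pfs_distribution = list(name = "fixed", days = 300),
    censor_rate = 0, missing_rate = 0, seed = 5))
  pre <- log(co$samples$concentration[co$samples$time_days < 0])
  se <- sd(pre) / sqrt(length(pre))
  expect_lt(abs(mean(pre) - 2.5), 3 * se)
})
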