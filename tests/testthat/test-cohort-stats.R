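test_that("Mann-Whitney matches enumeration, pwilcox and the normal path", {
  mw <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(mw$U, 0)
  expect_equal(mw$p_value, 1 / 3, tolerance = 1e-12)
  withr::local_seed(10)
  # tie-free and tied random cases against the brute-force oracle
  for (i in 1:20) {
    m <- sample(2:6, 1); n <- sample(2:6, 1)
    x <- rnorm(m); y <- rnorm(n)
    expect_equal(mann_whitney(x, y), mw_enumeration_oracle(x, y),
                 tolerance = 1e-12)
    xt <- sample(1:4, m, replace = TRUE); yt <- sample(1:4, n, replace = TRUE)
    expect_equal(mann_whitney(xt, yt), mw_enumeration_oracle(xt, yt),
                 tolerance = 1e-12)
  }
  # beyond the exact range: tie-corrected normal approximation
  x <- rnorm(30); y <- rnorm(25) + 0.5
  ref <- wilcox.test(x, y, exact = FALSE, correct = FALSE)
  expect_equal(mann_whitney(x, y)$p_value, ref$p.value, tolerance = 1e-12)
  expect_equal(mann_whitney(x, y)$U, unname(ref$statistic))
})

test_that("the Bonferroni family threshold is alpha over biomarkers x bins", {
  expect_equal(bonferroni_threshold(0.05, 15, 10), 0.05 / 150)
  expect_equal(signif(bonferroni_threshold(), 1), 3e-4)
  expect_equal(bonferroni_threshold(0.05, 3, 10), 0.05 / 30)
})

test_that("baseline normalisation anchors the series at zero log-ratio", {
  s <- to_normalized_series(c(-14, -1, 50), c(4, 6, 5), pfs_days = 100)
  expect_equal(s$log_ratio, c(0, 0))   # 5 equals the baseline mean of 4 and 6
  expect_equal(s$pct_pfs, c(0, 50))
  s2 <- to_normalized_series(c(-1, 100), c(10, 20), pfs_days = 100)
  expect_equal(s2$log_ratio[2], log(2))
  expect_equal(s2$pct_pfs[2], 100)     # progression sample sits at 100% PFS
  s3 <- to_normalized_series(-1, 10, pfs_days = 100)  # single pre-treatment draw
  expect_equal(nrow(s3), 1)
  expect_error(to_normalized_series(c(10, 20), c(1, 2), 100), "pre-treatment")
})

test_that("interval comparison bins, interpolates and reports min p", {
  # arms separated by a constant log-ratio offset in every bin
  mk <- function(id, arm, offset) tibble::tibble(
    patient_id = id, arm = arm,
    pct_pfs = c(0, 25, 50, 75, 100),
    log_ratio = c(0, offset + c(0.01, 0.02, 0.03, 0.04) * as.numeric(factor(id))))
  d <- dplyr::bind_rows(
    lapply(sprintf("s%d", 1:6), mk, arm = "standard", offset = 0),
    lapply(sprintf("e%d", 1:6), mk, arm = "experimental", offset = -2))
  ic <- interval_arm_comparison(d, n_biomarkers = 15)
  expect_equal(nrow(ic), 10)
  expect_equal(ic$n_standard, rep(6, 10))
  expect_lt(attr(ic, "min_p"), 0.01)
  expect_equal(attr(ic, "bonferroni"), 0.05 / 150)
  # identical arms stay above the corrected threshold in almost every replicate
  withr::local_seed(11)
  null_ok <- vapply(1:20, function(i) {
    d0 <- dplyr::bind_rows(lapply(1:16, function(j) tibble::tibble(
      patient_id = sprintf("p%d", j),
      arm = rep(c("standard", "experimental"), each = 8)[j],
      pct_pfs = c(0, sort(runif(5, 5, 100))),
      log_ratio = c(0, rnorm(5, 0, 0.5)))))
    attr(suppressWarnings(interval_arm_comparison(d0, n_biomarkers = 15)),
         "min_p") > 3e-4
  }, logical(1))
  expect_gte(sum(null_ok), 19)
})

test_that("normalized cohort series flow into the arm comparison", {
  co <- quick_cohort(n = 12, pfs = 300, spec = point_spec(noise_sd = 0.1),
                     seed = 12)
  nz <- normalize_cohort(co, "Tie2")
  expect_true(all(nz$pct_pfs >= 0 & nz$pct_pfs <= 100))
  expect_true(all(abs(nz$log_ratio[!duplicated(nz$patient_id)]) < 1e-12))
  ic <- interval_arm_comparison(nz, n_biomarkers = 1)
  expect_s3_class(ic, "interval_comparison")
})

test_that("response comparison applies the CR/SD, PR and Ca125 exclusions", {
  spec_t <- point_spec("Tie2", alpha = 3, beta = -0.3, gamma = 0.2,
                       noise_sd = 0.2)
  co <- quick_cohort(n = 16, pfs = 300, spec = spec_t, seed = 13)
  ids <- co$patients$patient_id
  resp <- tibble::tibble(
    patient_id = ids,
    response = rep(c("CR", "SD", "PR", "CR"), each = 4))
  out <- response_comparison(co, resp)
  expect_equal(out$n_cr, 8)  # PR patients appear in no comparison
  expect_equal(out$n_sd, 4)
  # identical CR/SD distributions: permuted labels rarely reach significance
  withr::local_seed(14)
  ps <- vapply(1:40, function(i) {
    labs <- tibble::tibble(patient_id = ids,
                           response = sample(rep(c("CR", "SD"), 8)))
    min(response_comparison(co, labs)$p_value)
  }, numeric(1))
  expect_gte(mean(ps > 0.05), 0.9)
  # low-baseline Ca125 patients are excluded from the Ca125 comparison
  ca <- manual_cohort(
    times_list = rep(list(c(-1, 30, 60)), 6),
    conc_list = c(rep(list(c(25, 40, 50)), 2),   # baseline < 30 IU/l
                  rep(list(c(100, 60, 50)), 4)),
    pfs = rep(90, 6), progressed = rep(FALSE, 6), biomarker = "Ca125")
  resp_ca <- tibble::tibble(patient_id = sprintf("M%02d", 1:6),
                            response = c("CR", "SD", "CR", "CR", "SD", "SD"))
  out_ca <- response_comparison(ca, resp_ca)
  expect_equal(out_ca$n_cr + out_ca$n_sd, 4)
})
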