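test_that("trajectory evaluation matches hand-computed piecewise values", {
  p <- piecewise_params(0, -2, 1, 5)
  expect_equal(evaluate_trajectory(p, 3), -6)
  expect_equal(evaluate_trajectory(p, 7), -8)   # -10 + 2
  expect_equal(evaluate_trajectory(p, 5), -10)  # equals both one-sided limits
  expect_equal(evaluate_trajectory(p, -2), 0)   # clipped at pre-treatment level
  expect_equal(evaluate_trajectory(p, c(3, 7)), c(-6, -8))
})

test_that("trajectory is continuous at the inflection for random parameters", {
  withr::local_seed(1)
  for (i in 1:200) {
    p <- piecewise_params(rnorm(1, 0, 3), rnorm(1, 0, 3), rnorm(1, 0, 3),
                          runif(1, 0.1, 12))
    left <- p$alpha + p$beta * p$t_inflection
    right <- p$alpha + p$beta * p$t_inflection + p$gamma * 0
    expect_lt(abs(left - right), 1e-12)
    expect_equal(evaluate_trajectory(p, p$t_inflection), left)
  }
})

test_that("log-likelihood agrees with a naive per-point density sum", {
  p <- piecewise_params(1, -0.5, 0.3, 4, sigma = 1)
  expect_equal(trajectory_log_likelihood(p, 2, evaluate_trajectory(p, 2)),
               -0.5 * log(2 * pi))
  expect_equal(trajectory_log_likelihood(p, c(2, 2.0001),
                                         evaluate_trajectory(p, c(2, 2.0001))),
               -log(2 * pi), tolerance = 1e-12)
  expect_equal(trajectory_log_likelihood(p, 2, evaluate_trajectory(p, 2) + 1),
               -0.5 * log(2 * pi) - 0.5)
  withr::local_seed(2)
  t <- runif(8, -1, 10); y <- rnorm(8)
  naive <- sum(vapply(seq_along(t), function(i)
    dnorm(y[i], evaluate_trajectory(p, t[i]), p$sigma, log = TRUE), numeric(1)))
  expect_equal(trajectory_log_likelihood(p, t, y), naive, tolerance = 1e-10)
  expect_error(trajectory_log_likelihood(piecewise_params(0, 0, 0, 1, 0), 1, 0),
               "sigma")
})

test_that("Ang1 x Tie2 composite is the product of Tie2 and log2 Ang1", {
  expect_equal(composite_ang1_tie2(10, 8), 30)
  expect_equal(composite_ang1_tie2(5, 1), 0)
  expect_equal(composite_ang1_tie2(5, 2), 5)
  expect_error(composite_ang1_tie2(5, 0), "positive")
  co <- quick_cohort(n = 4, pfs = 300,
                     spec = point_spec("Tie2", alpha = log(10)), seed = 1)
  ang <- quick_cohort(n = 4, pfs = 300,
                      spec = point_spec("Ang1", alpha = log(8)), seed = 1)
  co$samples <- dplyr::bind_rows(co$samples, ang$samples)
  cc <- add_composite_ang1_tie2(co)
  comp <- cc$samples[cc$samples$biomarker == "Ang1xTie2", ]
  expect_gt(nrow(comp), 0)
  expect_equal(comp$concentration[1], 10 * log2(8), tolerance = 1e-10)
})

test_that("hierarchical fit recovers a noiseless shared trajectory", {
  co <- quick_cohort(n = 6, pfs = 300,
                     spec = point_spec(alpha = 3, beta = -0.8, gamma = 0.5),
                     seed = 7)
  # near-degenerate noiseless posterior: Rhat screening may warn by design
  post <- suppressWarnings(
    fit_hierarchical(co, "Tie2", arm = "experimental",
                     mcmc = mcmc_settings(2, 300, 300, 500), seed = 1))
  expect_s3_class(post, "hier_posterior")
  expect_equal(mean(post$draws$mu_beta), -0.8, tolerance = 0.05)
  expect_equal(mean(post$draws$mu_gamma), 0.5, tolerance = 0.05)
  # patient-level inflection times near the generative 60% of PFS (6 months)
  expect_equal(unname(colMeans(post$draws$t_inflection)),
               rep(0.6 * 300 / 30, 3), tolerance = 0.15)
})

test_that("fit rejects insufficient data and unknown biomarkers", {
  co <- quick_cohort(n = 6)
  expect_error(fit_hierarchical(co, "VEGF"), "absent")
  sparse <- manual_cohort(
    times_list = list(c(-1, 30), c(-1, 40), c(-1, 50)),
    conc_list = list(c(10, 9), c(10, 8), c(10, 7)))
  expect_warning(
    expect_error(fit_hierarchical(sparse, "Tie2"), ">= 2 patients"),
    "dropping")
})

test_that("fitting is seed-reproducible and seed-robust", {
  co <- quick_cohort(n = 6, spec = point_spec(noise_sd = 0.2), seed = 3)
  ms <- mcmc_settings(2, 300, 300, 500)
  fit_quiet <- function(seed) suppressWarnings(
    fit_hierarchical(co, "Tie2", arm = "standard", mcmc = ms, seed = seed))
  a <- fit_quiet(11)
  b <- fit_quiet(11)
  expect_identical(a$draws, b$draws)
  c2 <- fit_quiet(12)
  expect_false(identical(a$draws$mu_beta, c2$draws$mu_beta))
  # posterior means agree within 3 x Monte-Carlo standard error
  for (g in c("mu_beta", "mu_gamma")) {
    da <- a$draws[[g]]; dc <- c2$draws[[g]]
    mcse <- sqrt(sd(da)^2 / coda::effectiveSize(coda::mcmc(da)) +
                   sd(dc)^2 / coda::effectiveSize(coda::mcmc(dc)))
    expect_lt(abs(mean(da) - mean(dc)), 3 * max(mcse, 1e-6))
  }
})
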