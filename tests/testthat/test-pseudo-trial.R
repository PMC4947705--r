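test_that("monthly imputation follows the 30-day grid and the trajectory", {
  p <- piecewise_params(log(100), -0.1, 0.3, 4, sigma = 0)
  cfg0 <- pseudo_trial_config(visit_jitter_days = 0, seed = 1)
  s <- impute_monthly(p, 100, cfg0)
  expect_equal(s$time_days, c(30, 60, 90))
  expect_equal(length(impute_monthly(p, 29, cfg0)$time_days), 0)
  # noiseless series is monotone increasing after the inflection (4 months)
  s2 <- impute_monthly(p, 400, cfg0)
  post <- s2$concentration[s2$time_days > 4 * 30]
  expect_true(all(diff(post) > 0))
  expect_equal(s2$concentration[1], 100 * exp(-0.1), tolerance = 1e-12)
  # jitter stays inside +/- 5 days of the grid
  cfg5 <- pseudo_trial_config(visit_jitter_days = 5, seed = 2)
  s3 <- impute_monthly(p, 400, cfg5, seed = 3)
  expect_true(all(abs(s3$time_days - 30 * seq_along(s3$time_days)) <= 5))
  expect_error(pseudo_trial_config(visit_jitter_days = 30), "interval")
})

test_that("pseudo-trajectories are joint draws from the patient's posterior", {
  deg <- degenerate_posterior("P1", alpha = 2, beta = -1, gamma = 0.5,
                              t_inflection_mo = 5, sigma = 0.1)
  d <- sample_pseudo_trajectory(deg, "P1", seed = 1)
  expect_equal(d[c("alpha", "beta", "gamma", "t_inflection", "sigma")],
               list(alpha = 2, beta = -1, gamma = 0.5, t_inflection = 5,
                    sigma = 0.1))
  expect_error(sample_pseudo_trajectory(deg, "NOPE"), "absent")
  # empirical mean over many draws approaches the posterior mean
  withr::local_seed(3)
  betas <- rnorm(400, -2, 0.5)
  post <- hier_posterior("P1", alpha = matrix(rnorm(400), 400),
                         beta = matrix(betas, 400),
                         gamma = matrix(rnorm(400), 400),
                         t_inflection = matrix(runif(400, 1, 9), 400),
                         sigma = rep(0.2, 400))
  draws <- vapply(1:2000, function(i)
    sample_pseudo_trajectory(post, "P1", seed = i)$beta, numeric(1))
  mcse <- sd(betas) / sqrt(2000)
  expect_lt(abs(mean(draws) - mean(betas)), 4 * mcse)
})

test_that("flat trajectories never alarm and rising ones always do", {
  ids <- sprintf("P%d", 1:6)
  patients <- tibble::tibble(patient_id = ids, pfs_days = 300, progressed = TRUE)
  flat <- degenerate_posterior(ids, alpha = log(100), beta = 0, gamma = 0,
                               t_inflection_mo = 5)
  cfg <- pseudo_trial_config(n_replicates = 100, seed = 4)
  r0 <- run_pseudo_trials(flat, patients, alarm_rule("Tie2", 0.5), cfg)
  expect_equal(r0$evaluation$prediction_rate, 0)
  rising <- degenerate_posterior(ids, alpha = log(100), beta = -0.1,
                                 gamma = 0.235, t_inflection_mo = 5)
  r1 <- run_pseudo_trials(rising, patients, alarm_rule("Tie2", 0.5), cfg)
  expect_equal(r1$evaluation$prediction_rate, 100)
  # deterministic given the config seed
  r2 <- run_pseudo_trials(rising, patients, alarm_rule("Tie2", 0.5), cfg)
  expect_identical(r1$per_patient, r2$per_patient)
  expect_error(run_pseudo_trials(rising, patients, alarm_rule("Ca125", 1), cfg),
               "missing posterior")
})

test_that("OR-combined rules dominate their components", {
  ids <- sprintf("P%d", 1:8)
  patients <- tibble::tibble(patient_id = ids, pfs_days = 300, progressed = TRUE)
  cfg <- pseudo_trial_config(n_replicates = 200, seed = 5)
  # noisy trajectories so neither component is saturated
  tie2 <- degenerate_posterior(ids, alpha = log(20), beta = -0.2, gamma = 0.1,
                               t_inflection_mo = 6, sigma = 0.25,
                               biomarker = "Tie2")
  ca <- degenerate_posterior(ids, alpha = log(300), beta = -0.5, gamma = 0.15,
                             t_inflection_mo = 5, sigma = 0.3,
                             biomarker = "Ca125")
  posts <- list(Tie2 = tie2, Ca125 = ca)
  rules <- list(alarm_rule("Tie2", 0.5), alarm_rule("Ca125", 1.0))
  both <- run_pseudo_trials(posts, patients, rules, cfg)
  one <- run_pseudo_trials(posts["Tie2"], patients, rules[1], cfg)
  two <- run_pseudo_trials(posts["Ca125"], patients, rules[2], cfg)
  expect_gte(both$evaluation$prediction_rate, one$evaluation$prediction_rate)
  expect_gte(both$evaluation$prediction_rate, two$evaluation$prediction_rate)
  expect_true(all(one$evaluation$prediction_rate > 0,
                  one$evaluation$prediction_rate < 100))
})

test_that("Monte-Carlo error of alarm probabilities shrinks like 1/sqrt(n)", {
  patients <- tibble::tibble(patient_id = "P1", pfs_days = 300, progressed = TRUE)
  post <- degenerate_posterior("P1", alpha = log(50), beta = -0.25, gamma = 0.12,
                               t_inflection_mo = 6, sigma = 0.3)
  prob_at <- function(reps, seed) {
    cfg <- pseudo_trial_config(n_replicates = reps, seed = seed)
    run_pseudo_trials(post, patients, alarm_rule("Tie2", 0.5),
                      cfg)$per_patient$alarm_probability
  }
  p_small <- vapply(1:15, function(s) prob_at(100, s), numeric(1))
  p_big <- vapply(1:15, function(s) prob_at(1600, 100 + s), numeric(1))
  ratio <- sd(p_small) / sd(p_big)
  expect_gt(ratio, 4 / 2.2)  # expected 4, allow generous Monte-Carlo slack
  expect_lt(ratio, 4 * 2.2)
})

test_that("pseudo-trial threshold sweep is consistent with direct runs", {
  ids <- sprintf("P%d", 1:5)
  patients <- tibble::tibble(patient_id = ids, pfs_days = 300, progressed = TRUE)
  post <- degenerate_posterior(ids, alpha = log(50), beta = -0.25, gamma = 0.2,
                               t_inflection_mo = 6, sigma = 0.2)
  cfg <- pseudo_trial_config(n_replicates = 150, seed = 6)
  sw <- pseudo_trial_sweep(post, patients, thresholds = c(0.3, 0.5, 1.0), cfg)
  expect_equal(nrow(sw), 3)
  expect_true(all(diff(sw$prediction_rate) <= 0))
  direct <- run_pseudo_trials(post, patients, alarm_rule("Tie2", 0.5), cfg)
  expect_equal(sw$prediction_rate[2], direct$evaluation$prediction_rate)
})
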