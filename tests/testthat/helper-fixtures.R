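# Shared fixtures: tiny cohorts and oracles built in code.

# single-biomarker spec with every hierarchy SD at zero: all patients share
# one exact piecewise line (for recovery and arithmetic checks)
point_spec <- function(name = "Tie2", alpha = 3, beta = -0.8, gamma = 0.5,
                       inflection_fraction = 0.6, noise_sd = 0,
                       arm_equal = TRUE) {
  biomarker_spec(
    name,
    baseline_log_mean = alpha, baseline_log_sd = 0,
    slope_before_mean = c(standard = beta, experimental = beta),
    slope_after_mean = c(standard = gamma, experimental = gamma),
    slope_sd = 0,
    inflection_fraction_mean = inflection_fraction,
    inflection_fraction_sd = 0,
    noise_sd = noise_sd)
}

quick_cohort <- function(n = 6, pfs = 300, spec = point_spec(), seed = 42,
                         missing_rate = 0, censor_rate = 0) {
  generate_cohort(cohort_config(
    n_standard = max(1, n %/% 2), n_experimental = max(1, n - n %/% 2),
    biomarkers = setNames(list(spec), spec$name),
    pfs_distribution = list(name = "fixed", days = pfs),
    censor_rate = censor_rate, missing_rate = missing_rate, seed = seed))
}

# hand-build a cohort from per-patient visit vectors (bypasses the generator)
manual_cohort <- function(times_list, conc_list, arms = NULL, pfs = NULL,
                          progressed = NULL, biomarker = "Tie2") {
  n <- length(times_list)
  arms <- arms %||% rep("standard", n)
  pfs <- pfs %||% vapply(times_list, max, numeric(1))
  progressed <- progressed %||% rep(TRUE, n)
  ids <- sprintf("M%02d", seq_len(n))
  samples <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    tibble::tibble(
      patient_id = ids[i], arm = arms[i], biomarker = biomarker,
      time_days = times_list[[i]], concentration = conc_list[[i]],
      visit_label = paste0("v", seq_along(times_list[[i]])),
      is_progression_sample = progressed[i] &
        seq_along(times_list[[i]]) == length(times_list[[i]]) &
        times_list[[i]] == pfs[i])
  }))
  patients <- tibble::tibble(patient_id = ids, arm = arms, pfs_days = pfs,
                             progressed = progressed)
  angiotraj:::new_biomarker_cohort(samples, patients)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# degenerate (point-mass) posterior shared across pseudo-trial tests
degenerate_posterior <- function(patients, alpha, beta, gamma, t_inflection_mo,
                                 sigma = 0, biomarker = "Tie2") {
  np <- length(patients)
  hier_posterior(patients,
                 alpha = rep(alpha, length.out = np),
                 beta = rep(beta, length.out = np),
                 gamma = rep(gamma, length.out = np),
                 t_inflection = rep(t_inflection_mo, length.out = np),
                 sigma = sigma, biomarker = biomarker)
}

# independent brute-force Mann-Whitney: enumerate every assignment of m pooled
# values to group x, U from explicit pairwise comparisons, two-sided by
# distance of U from its null mean
mw_enumeration_oracle <- function(x, y) {
  m <- length(x); n <- length(y)
  z <- c(x, y)
  u_of <- function(idx) {
    a <- z[idx]; b <- z[-idx]
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  U <- u_of(seq_len(m))
  Uperm <- apply(combn(m + n, m), 2, u_of)
  list(U = U,
       p_value = mean(abs(Uperm - m * n / 2) >= abs(U - m * n / 2) - 1e-9))
}
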