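#' Pseudo-trial simulation settings
#'
#' Posterior-predictive replicates of each existing patient's trajectory,
#' re-observed on a monthly monitoring schedule (30 +/- 5 days by default,
#' jitter uniform), 5000 replicates per patient per biomarker by default.
#'
#' @param n_replicates Replicates per patient per biomarker.
#' @param visit_interval_days Monitoring interval in days.
#' @param visit_jitter_days Half-width of the uniform jitter around each
#'   scheduled visit; must be smaller than the interval.
#' @param seed Integer seed for the whole pseudo-trial run.
#' @param aggregate How a patient counts as predicted at cohort level:
#'   `"mean"` averages per-patient alarm probabilities; `"majority"` counts a
#'   patient when at least half the replicates alarm.
#' @return A list of class `pseudo_trial_config`.
#' @export
pseudo_trial_config <- function(n_replicates = 5000, visit_interval_days = 30,
                                visit_jitter_days = 5, seed = 1L,
                                aggregate = c("mean", "majority")) {
  abort_if(!is_scalar_number(n_replicates) || n_replicates < 1,
           "`n_replicates` must be >= 1")
  abort_if(visit_jitter_days < 0 || visit_jitter_days >= visit_interval_days,
           "jitter must be in [0, interval)")
  structure(list(n_replicates = as.integer(n_replicates),
                 visit_interval_days = visit_interval_days,
                 visit_jitter_days = visit_jitter_days,
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 aggregate = match.arg(aggregate)),
            class = "pseudo_trial_config")
}

#' Draw one patient's parameters from a fitted posterior
#'
#' Takes one joint draw of the patient's trajectory parameters (and the
#' residual SD) from the posterior — pseudo-trials replay existing patients,
#' never new pseudo-patients.
#'
#' @param posterior A `hier_posterior`.
#' @param patient_id Patient present in the posterior.
#' @param seed Optional replicate seed.
#' @return A [piecewise_params()] (t_inflection in months).
#' @export
sample_pseudo_trajectory <- function(posterior, patient_id, seed = NULL) {
  stopifnot(inherits(posterior, "hier_posterior"))
  abort_if(!patient_id %in% posterior$patients,
           sprintf("patient '%s' absent from posterior", patient_id))
  d <- posterior$draws
  k <- with_seed(seed, sample.int(length(d$sigma), 1))
  piecewise_params(alpha = unname(d$alpha[k, patient_id]),
                   beta = unname(d$beta[k, patient_id]),
                   gamma = unname(d$gamma[k, patient_id]),
                   t_inflection = unname(max(d$t_inflection[k, patient_id], 1e-9)),
                   sigma = unname(d$sigma[k]))
}

#' Impute a monthly monitored series from trajectory parameters
#'
#' Places monitoring visits at `interval * k` days (k = 1, 2, ...) up to
#' `pfs_days`, jitters each by the configured uniform offset, and draws a
#' posterior-predictive concentration at each visit:
#' `exp(trajectory + Normal(0, sigma))`.
#'
#' @param params A [piecewise_params()].
#' @param pfs_days Positive monitoring horizon in days.
#' @param config A [pseudo_trial_config()].
#' @param seed Optional seed.
#' @return A [monitored_series()]; empty when `pfs_days` is below one
#'   interval.
#' @export
impute_monthly <- function(params, pfs_days, config = pseudo_trial_config(),
                           seed = NULL) {
  abort_if(!is_scalar_number(pfs_days) || pfs_days <= 0,
           "`pfs_days` must be positive")
  K <- floor(pfs_days / config$visit_interval_days)
  if (K < 1) {
    return(monitored_series(numeric(0), numeric(0), pfs_days = pfs_days))
  }
  with_seed(seed, {
    j <- config$visit_jitter_days
    times <- config$visit_interval_days * seq_len(K) +
      if (j > 0) runif(K, -j, j) else 0
    conc <- exp(evaluate_trajectory(params, times / DAYS_PER_MONTH) +
                  rnorm(K, 0, params$sigma))
    monitored_series(times, conc, pfs_days = pfs_days)
  })
}

# Simulate the replicate-by-visit concentration matrix for one patient:
# each row is one posterior draw re-observed on the jittered monthly grid.
simulate_patient_matrix <- function(posterior, patient_id, pfs_days, config,
                                    seed) {
  d <- posterior$draws
  K <- floor(pfs_days / config$visit_interval_days)
  R <- config$n_replicates
  with_seed(seed, {
    ks <- sample.int(length(d$sigma), R, replace = TRUE)
    if (K < 1) {
      return(list(times = matrix(0, R, 0), values = matrix(0, R, 0)))
    }
    jit <- if (config$visit_jitter_days > 0) {
      matrix(runif(R * K, -config$visit_jitter_days, config$visit_jitter_days),
             R, K)
    } else matrix(0, R, K)
    times <- matrix(config$visit_interval_days * seq_len(K), R, K,
                    byrow = TRUE) + jit
    tm <- times / DAYS_PER_MONTH
    alpha <- d$alpha[ks, patient_id]
    beta <- d$beta[ks, patient_id]
    gamma <- d$gamma[ks, patient_id]
    tin <- pmax(d$t_inflection[ks, patient_id], 1e-9)
    mu <- alpha + beta * pmin(tm, tin) + (tm > tin) * gamma * (tm - tin)
    noise <- matrix(rnorm(R * K), R, K) * d$sigma[ks]
    list(times = times, values = exp(mu + noise))
  })
}

# first alarm column per row under a nadir-elevation threshold; vectorised
# running minimum across columns. Returns integer vector (NA = no alarm).
alarm_col_matrix <- function(values, threshold_fraction) {
  R <- nrow(values); K <- ncol(values)
  if (K == 0) return(rep(NA_integer_, R))
  runmin <- values[, 1]
  hit <- matrix(FALSE, R, K)
  for (k in seq_len(K)) {
    runmin <- pmin(runmin, values[, k])
    hit[, k] <- values[, k] >= runmin * (1 + threshold_fraction)
  }
  first <- max.col(hit, ties.method = "first")
  first[!hit[cbind(seq_len(R), first)]] <- NA_integer_
  first
}

#' Run posterior-driven pseudo-trials through the alarm rules
#'
#' For every progressed patient, draws `n_replicates` posterior-predictive
#' trajectory replicates per biomarker, re-observes them on the monthly
#' monitoring grid, applies the given nadir-elevation rules (multiple rules
#' are OR-combined: earliest component alarm wins) and aggregates replicate
#' alarms into a per-patient alarm probability and a cohort-level
#' [evaluate_rule_over_cohort()]-style summary.
#'
#' @param posteriors A `hier_posterior` or a named list of them (names =
#'   biomarker) covering every rule's biomarker.
#' @param patients Tibble with `patient_id`, `pfs_days`, `progressed`.
#' @param rules An [alarm_rule()] or list of them.
#' @param config A [pseudo_trial_config()].
#' @return List of class `pseudo_trial_result`: `per_patient` tibble
#'   (`patient_id`, `alarm_probability`, `mean_alarm_pct_pfs`), `evaluation`
#'   (one-row cohort summary), `rules`, `config`.
#' @export
run_pseudo_trials <- function(posteriors, patients, rules,
                              config = pseudo_trial_config()) {
  if (inherits(posteriors, "hier_posterior")) {
    posteriors <- setNames(list(posteriors), posteriors$biomarker)
  }
  if (inherits(rules, "alarm_rule")) rules <- list(rules)
  need <- vapply(rules, `[[`, character(1), "biomarker")
  abort_if(!all(need %in% names(posteriors)),
           sprintf("missing posterior for biomarker(s): %s",
                   paste(setdiff(need, names(posteriors)), collapse = ", ")))
  patients <- as_tibble(patients)
  patients <- patients[patients$progressed %in% TRUE, ]
  abort_if(nrow(patients) == 0, "no progressed patients")
  pres <- lapply(seq_len(nrow(patients)), function(i) {
    p <- patients[i, ]
    # earliest alarm across rules, per replicate
    alarm_time <- NULL
    for (ri in seq_along(rules)) {
      rule <- rules[[ri]]
      post <- posteriors[[rule$biomarker]]
      abort_if(!p$patient_id %in% post$patients,
               sprintf("patient '%s' absent from %s posterior",
                       p$patient_id, rule$biomarker))
      sim <- simulate_patient_matrix(post, p$patient_id, p$pfs_days, config,
                                     seed = child_seed(config$seed, i, ri))
      cols <- alarm_col_matrix(sim$values, rule$threshold_fraction)
      at <- ifelse(is.na(cols), NA_real_,
                   sim$times[cbind(seq_along(cols), cols)])
      alarm_time <- if (is.null(alarm_time)) at else pmin(alarm_time, at, na.rm = TRUE)
    }
    ok <- !is.na(alarm_time) & alarm_time <= p$pfs_days
    tibble(patient_id = p$patient_id,
           alarm_probability = mean(ok),
           mean_alarm_pct_pfs = if (any(ok))
             mean(100 * alarm_time[ok] / p$pfs_days) else NA_real_)
  })
  per_patient <- bind_rows(pres)
  prob <- per_patient$alarm_probability
  rate <- switch(config$aggregate,
                 mean = 100 * mean(prob),
                 majority = 100 * mean(prob >= 0.5))
  alarmed <- !is.na(per_patient$mean_alarm_pct_pfs)
  evaluation <- tibble(
    threshold_fraction = if (length(rules) == 1)
      rules[[1]]$threshold_fraction else NA_real_,
    prediction_rate = rate,
    mean_prediction_time = if (any(alarmed))
      mean(per_patient$mean_alarm_pct_pfs[alarmed]) else NA_real_,
    sd_prediction_time = if (sum(alarmed) > 1)
      sd(per_patient$mean_alarm_pct_pfs[alarmed]) else NA_real_,
    n_predicted = sum(prob >= 0.5),
    n_progressed = nrow(per_patient))
  class(evaluation) <- c("rule_evaluation", class(evaluation))
  structure(list(per_patient = per_patient, evaluation = evaluation,
                 rules = rules, config = config),
            class = "pseudo_trial_result")
}

#' @export
print.pseudo_trial_result <- function(x, ...) {
  rl <- paste(vapply(x$rules, function(r)
    sprintf("%s>%.0f%%", r$biomarker, 100 * r$threshold_fraction),
    character(1)), collapse = " OR ")
  e <- x$evaluation
  cat(sprintf(
    "<pseudo_trial_result> %s: predicted %.1f%% of %d patients at %.1f%% +/- %.1f %%PFS (%d reps)\n",
    rl, e$prediction_rate, e$n_progressed, e$mean_prediction_time,
    e$sd_prediction_time, x$config$n_replicates))
  invisible(x)
}

#' Threshold sweep over pseudo-trials for one biomarker
#'
#' Simulates each patient's replicate matrix once and evaluates every
#' threshold on it, giving the prediction-rate versus prediction-quality
#' curve of the biomarker under monthly monitoring.
#'
#' @param posterior A `hier_posterior`.
#' @param patients Tibble with `patient_id`, `pfs_days`, `progressed`.
#' @param thresholds Positive threshold fractions.
#' @param config A [pseudo_trial_config()].
#' @return Tibble of class `threshold_sweep`, one row per threshold.
#' @export
pseudo_trial_sweep <- function(posterior, patients,
                               thresholds = seq(0.1, 1.5, by = 0.1),
                               config = pseudo_trial_config()) {
  stopifnot(inherits(posterior, "hier_posterior"))
  abort_if(any(thresholds <= 0), "`threshold_fraction` must be > 0")
  patients <- as_tibble(patients)
  patients <- patients[patients$progressed %in% TRUE, ]
  abort_if(nrow(patients) == 0, "no progressed patients")
  sims <- lapply(seq_len(nrow(patients)), function(i) {
    simulate_patient_matrix(posterior, patients$patient_id[i],
                            patients$pfs_days[i], config,
                            seed = child_seed(config$seed, i, 1L))
  })
  out <- lapply(thresholds, function(th) {
    rows <- lapply(seq_along(sims), function(i) {
      sim <- sims[[i]]
      cols <- alarm_col_matrix(sim$values, th)
      at <- ifelse(is.na(cols), NA_real_,
                   sim$times[cbind(seq_along(cols), cols)])
      ok <- !is.na(at) & at <= patients$pfs_days[i]
      c(prob = mean(ok),
        pct = if (any(ok)) mean(100 * at[ok] / patients$pfs_days[i]) else NA_real_)
    })
    m <- do.call(rbind, rows)
    alarmed <- !is.na(m[, "pct"])
    tibble(threshold_fraction = th,
           prediction_rate = switch(config$aggregate,
                                    mean = 100 * mean(m[, "prob"]),
                                    majority = 100 * mean(m[, "prob"] >= 0.5)),
           mean_prediction_time = if (any(alarmed))
             mean(m[alarmed, "pct"]) else NA_real_,
           sd_prediction_time = if (sum(alarmed) > 1)
             sd(m[alarmed, "pct"]) else NA_real_,
           n_predicted = sum(m[, "prob"] >= 0.5),
           n_progressed = nrow(m))
  })
  out <- bind_rows(out)
  class(out) <- c("threshold_sweep", class(out))
  out
}

#' Write per-patient pseudo-trial results as CSV
#'
#' @param result A `pseudo_trial_result`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_pseudo_trial <- function(result, path) {
  stopifnot(inherits(result, "pseudo_trial_result"))
  pp <- result$per_patient
  pp$biomarkers <- paste(vapply(result$rules, `[[`, character(1), "biomarker"),
                         collapse = "|")
  pp$threshold <- paste(vapply(result$rules, function(r)
    format(r$threshold_fraction), character(1)), collapse = "|")
  readr::write_csv(pp, path)
  invisible(path)
}
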