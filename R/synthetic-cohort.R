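# ICON7-style visit grid, in days from treatment start. Labels follow the
# trial's sampling plan (two pre-treatment draws, end of cycle-1 infusion,
# pre-cycle-2, pre-cycle-6, end of cycle-6 infusion, then 6/9/12 months); the
# day values are a reconstruction of the 3-weekly cycle calendar.
default_visit_grid <- function() {
  tibble(
    visit_label = c("pretreatment_1", "pretreatment_2", "cycle1_end",
                    "precycle_2", "precycle_6", "cycle6_end",
                    "month_6", "month_9", "month_12"),
    time_days = c(-14, -1, 0, 21, 105, 126, 183, 274, 365))
}

#' Scheduled sampling visits for one patient
#'
#' Returns the trial visit grid truncated at the patient's progression-free
#' survival, with a progression sample appended at `pfs_days` when the patient
#' progressed. Up to 10 visits result: two pre-treatment draws, seven
#' on-treatment draws and the progression draw.
#'
#' @param pfs_days Progression-free survival in days; must be positive.
#' @param progressed Logical; if `TRUE` a `"progression"` visit at `pfs_days`
#'   is appended.
#' @param grid Visit grid (tibble with `visit_label`, `time_days`); defaults
#'   to the ICON7-style calendar.
#' @return Tibble with columns `visit_label`, `time_days`,
#'   `is_progression_sample`.
#' @export
sampling_schedule <- function(pfs_days, progressed = TRUE,
                              grid = default_visit_grid()) {
  abort_if(!is_scalar_number(pfs_days) || pfs_days <= 0,
           "`pfs_days` must be a positive number")
  out <- grid[grid$time_days < pfs_days, ]
  out$is_progression_sample <- FALSE
  if (isTRUE(progressed)) {
    out <- bind_rows(out, tibble(visit_label = "progression",
                                 time_days = pfs_days,
                                 is_progression_sample = TRUE))
  }
  out
}

#' Simulate measured concentrations along a trajectory
#'
#' Evaluates the piecewise-linear log-trajectory at the scheduled times
#' (pre-treatment visits sit at the `alpha` level) and adds Gaussian
#' measurement noise on the log scale, returning concentrations.
#'
#' @param params A [piecewise_params()] object.
#' @param schedule_days Visit times in days from treatment start (negative for
#'   pre-treatment draws).
#' @param noise_sd Residual SD on the log scale; overrides `params$sigma` when
#'   given.
#' @param seed Optional integer seed.
#' @return Numeric vector of concentrations, one per visit.
#' @export
generate_patient_trajectory <- function(params, schedule_days,
                                        noise_sd = params$sigma, seed = NULL) {
  abort_if(length(schedule_days) == 0, "`schedule_days` must be non-empty")
  mu <- evaluate_trajectory(params, schedule_days / DAYS_PER_MONTH)
  with_seed(seed, exp(mu + rnorm(length(mu), 0, noise_sd)))
}

#' Generate a synthetic two-arm longitudinal cohort
#'
#' Draws patient-level trajectory parameters from the biomarker-level
#' hierarchies in `config`, simulates concentrations on the trial visit grid,
#' induces cross-biomarker correlation through shared within-block latent
#' factors at each blood draw, and drops scheduled on-treatment visits
#' independently at `missing_rate` (pre-treatment and progression draws are
#' never dropped). Fully reproducible from `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return A `biomarker_cohort`: list with tibbles `samples` (columns
#'   `patient_id`, `arm`, `biomarker`, `time_days`, `concentration`,
#'   `visit_label`, `is_progression_sample`) and `patients` (`patient_id`,
#'   `arm`, `pfs_days`, `progressed`), plus the generating `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  n <- config$n_standard + config$n_experimental
  patients <- tibble(
    patient_id = sprintf("P%03d", seq_len(n)),
    arm = rep(c("standard", "experimental"),
              c(config$n_standard, config$n_experimental)),
    pfs_days = draw_pfs(config$pfs_distribution, n),
    progressed = rbinom(n, 1, 1 - config$censor_rate) == 1)

  specs <- config$biomarkers
  blocks <- vapply(specs, `[[`, character(1), "correlation_block")

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    p <- patients[i, ]
    sched <- sampling_schedule(p$pfs_days, p$progressed)
    nv <- nrow(sched)
    # latent factors: one per block per blood draw (residual correlation) and
    # one per block per patient (baseline correlation)
    zf <- matrix(rnorm(nv * length(unique(blocks))), nv,
                 dimnames = list(NULL, unique(blocks)))
    zp <- setNames(rnorm(length(unique(blocks))), unique(blocks))
    per_bm <- vector("list", length(specs))
    for (b in seq_along(specs)) {
      sp <- specs[[b]]
      lam <- sp$factor_loading
      alpha <- sp$baseline_log_mean + sp$baseline_log_sd *
        (lam * zp[[sp$correlation_block]] + sqrt(1 - lam^2) * rnorm(1))
      beta <- rnorm(1, sp$slope_before_mean[[p$arm]], sp$slope_sd)
      gamma <- rnorm(1, sp$slope_after_mean[[p$arm]], sp$slope_sd)
      frac <- min(max(rnorm(1, sp$inflection_fraction_mean,
                            sp$inflection_fraction_sd), 0.05), 0.95)
      pars <- piecewise_params(alpha, beta, gamma,
                               t_inflection = frac * p$pfs_days / DAYS_PER_MONTH,
                               sigma = sp$noise_sd)
      resid <- sp$noise_sd *
        (lam * zf[, sp$correlation_block] + sqrt(1 - lam^2) * rnorm(nv))
      mu <- evaluate_trajectory(pars, sched$time_days / DAYS_PER_MONTH)
      per_bm[[b]] <- tibble(
        patient_id = p$patient_id, arm = p$arm, biomarker = sp$name,
        time_days = sched$time_days,
        concentration = exp(mu + resid),
        visit_label = sched$visit_label,
        is_progression_sample = sched$is_progression_sample)
    }
    dat <- bind_rows(per_bm)
    if (config$missing_rate > 0) {
      droppable <- sched$time_days >= 0 & !sched$is_progression_sample
      drop <- droppable & runif(nv) < config$missing_rate
      dat <- dat[!(dat$time_days %in% sched$time_days[drop]), ]
    }
    rows[[i]] <- dat
  }

  new_biomarker_cohort(bind_rows(rows), patients, config)
}
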