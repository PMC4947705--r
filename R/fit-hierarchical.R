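# Hierarchical piecewise-linear changepoint model, JAGS dialect.
#
# Observation j of patient pat[j] at time t[j] (months, pre-treatment times
# clipped to 0 so pre-treatment draws are replicates of alpha):
#   y[j] ~ Normal(alpha_i + beta_i*min(t, tin_i) + 1{t > tin_i}*gamma_i*(t - tin_i), sigma)
# Patient parameters are exchangeable draws from group-level normals; the
# inflection time is uniform on (0, last observation time of the patient).
# sigma is truncated below at 1e-4 so the likelihood stays evaluable on
# (near-)noiseless data.
hier_model_string <- function() {
  "model {
  for (j in 1:Nobs) {
    y[j] ~ dnorm(mu[j], tau)
    mu[j] <- alpha[pat[j]] + beta[pat[j]] * min(t[j], tin[pat[j]]) +
             step(t[j] - tin[pat[j]]) * gamma[pat[j]] * (t[j] - tin[pat[j]])
  }
  for (i in 1:Npat) {
    alpha[i] ~ dnorm(mu_alpha, tau_alpha)
    beta[i]  ~ dnorm(mu_beta,  tau_beta)
    gamma[i] ~ dnorm(mu_gamma, tau_gamma)
    tin[i]   ~ dunif(0, tmax[i])
  }
  mu_alpha ~ dnorm(0, prec_group)
  mu_beta  ~ dnorm(0, prec_group)
  mu_gamma ~ dnorm(0, prec_group)
  sd_alpha ~ dnorm(0, prec_sd) T(0,)
  sd_beta  ~ dnorm(0, prec_sd) T(0,)
  sd_gamma ~ dnorm(0, prec_sd) T(0,)
  sigma    ~ dnorm(0, prec_sigma) T(1.0E-4,)
  tau_alpha <- 1 / (sd_alpha * sd_alpha)
  tau_beta  <- 1 / (sd_beta * sd_beta)
  tau_gamma <- 1 / (sd_gamma * sd_gamma)
  tau       <- 1 / (sigma * sigma)
}"
}

GROUP_PARAMS <- c("mu_alpha", "mu_beta", "mu_gamma",
                  "sd_alpha", "sd_beta", "sd_gamma", "sigma")

#' MCMC settings for the hierarchical trajectory model
#'
#' @param n_chains Number of chains (>= 2 enables potential-scale-reduction
#'   diagnostics).
#' @param n_adapt Adaptation iterations.
#' @param n_warmup Burn-in iterations discarded after adaptation.
#' @param n_draws Retained draws per chain.
#' @return A list of settings for [fit_hierarchical()].
#' @export
mcmc_settings <- function(n_chains = 2, n_adapt = 500, n_warmup = 500,
                          n_draws = 1000) {
  list(n_chains = as.integer(n_chains), n_adapt = as.integer(n_adapt),
       n_warmup = as.integer(n_warmup), n_draws = as.integer(n_draws))
}

#' Fit the hierarchical Bayesian piecewise-linear trajectory model
#'
#' Models natural-log concentrations of one biomarker as patient-level
#' piecewise-linear trajectories with an unknown inflection point, patient
#' parameters drawn from arm-level normal hierarchies, fitted by Gibbs/slice
#' MCMC (JAGS). Arms are fitted separately (pass `arm`); priors are the
#' weakly-informative defaults Normal(0, 10^2) for group means, Half-Normal(5)
#' for between-patient SDs and Half-Normal(2) for the residual SD.
#'
#' Patients need at least 3 post-treatment observations; patients below that
#' are dropped with a warning and fitting stops if fewer than 2 remain.
#' Convergence is screened by the potential scale reduction factor of the
#' group-level parameters; values above 1.1 raise a warning, never an error.
#'
#' @param cohort A `biomarker_cohort`.
#' @param biomarker Biomarker to fit.
#' @param arm `"standard"`, `"experimental"` or `NULL` (pool both arms).
#' @param mcmc Settings from [mcmc_settings()].
#' @param seed Integer seed; draws are reproducible given the seed.
#' @param priors Optional overrides: `prec_group`, `prec_sd`, `prec_sigma`
#'   (precisions of the three prior families).
#' @param quiet Suppress JAGS progress output.
#' @return A `hier_posterior`: per-patient draw matrices (`alpha`, `beta`,
#'   `gamma`, `t_inflection` in months), group-level draw vectors, Rhat per
#'   group parameter, and chain metadata.
#' @export
fit_hierarchical <- function(cohort, biomarker, arm = NULL,
                             mcmc = mcmc_settings(), seed = 1L,
                             priors = list(), quiet = TRUE) {
  stopifnot(inherits(cohort, "biomarker_cohort"))
  s <- cohort$samples
  abort_if(!biomarker %in% s$biomarker,
           sprintf("biomarker '%s' absent from dataset", biomarker))
  s <- s[s$biomarker == biomarker, ]
  if (!is.null(arm)) {
    abort_if(!arm %in% c("standard", "experimental"), "unknown arm")
    s <- s[s$arm == arm, ]
    abort_if(nrow(s) == 0, sprintf("no '%s' samples in arm '%s'", biomarker, arm))
  }
  npost <- tapply(s$time_days >= 0, s$patient_id, sum)
  keep <- names(npost)[npost >= 3]
  if (length(keep) < length(npost)) {
    warning(sprintf("dropping %d patient(s) with < 3 post-treatment observations",
                    length(npost) - length(keep)), call. = FALSE)
  }
  abort_if(length(keep) < 2,
           "need >= 2 patients with >= 3 post-treatment observations each")
  s <- s[s$patient_id %in% keep, ]

  pat_ids <- sort(unique(s$patient_id))
  pat <- match(s$patient_id, pat_ids)
  tmo <- pmax(s$time_days, 0) / DAYS_PER_MONTH
  abort_if(any(s$concentration <= 0), "non-positive values cannot be log-modelled")
  pr <- modifyList(list(prec_group = 0.01, prec_sd = 0.04, prec_sigma = 0.25),
                   priors)
  jd <- list(y = log(s$concentration), t = tmo, pat = pat,
             Nobs = nrow(s), Npat = length(pat_ids),
             tmax = as.numeric(tapply(tmo, pat, max)),
             prec_group = pr$prec_group, prec_sd = pr$prec_sd,
             prec_sigma = pr$prec_sigma)
  inits <- lapply(seq_len(mcmc$n_chains), function(ch) {
    list(tin = jd$tmax / 2, mu_beta = 0, mu_gamma = 0,
         .RNG.name = "base::Mersenne-Twister",
         .RNG.seed = child_seed(seed, ch))
  })
  run <- function() {
    model <- rjags::jags.model(textConnection(hier_model_string()), data = jd,
                               inits = inits, n.chains = mcmc$n_chains,
                               n.adapt = mcmc$n_adapt, quiet = TRUE)
    update(model, mcmc$n_warmup, progress.bar = "none")
    rjags::coda.samples(model,
                        c("alpha", "beta", "gamma", "tin", GROUP_PARAMS),
                        n.iter = mcmc$n_draws, progress.bar = "none")
  }
  samp <- if (quiet) suppressWarnings(run()) else run()

  rhat <- rep(NA_real_, length(GROUP_PARAMS))
  names(rhat) <- GROUP_PARAMS
  if (mcmc$n_chains >= 2) {
    gd <- try(coda::gelman.diag(samp[, GROUP_PARAMS], autoburnin = FALSE,
                                multivariate = FALSE), silent = TRUE)
    if (!inherits(gd, "try-error")) rhat[] <- gd$psrf[GROUP_PARAMS, 1]
    bad <- names(rhat)[!is.na(rhat) & rhat > 1.1]
    if (length(bad)) {
      warning(sprintf("possible non-convergence (Rhat > 1.1): %s",
                      paste(bad, collapse = ", ")), call. = FALSE)
    }
  }

  m <- as.matrix(samp)  # chains stacked row-wise
  col_block <- function(stub) {
    cols <- paste0(stub, "[", seq_along(pat_ids), "]")
    out <- m[, cols, drop = FALSE]
    colnames(out) <- pat_ids
    out
  }
  draws <- list(alpha = col_block("alpha"), beta = col_block("beta"),
                gamma = col_block("gamma"), t_inflection = col_block("tin"),
                sigma = m[, "sigma"])
  for (g in setdiff(GROUP_PARAMS, "sigma")) draws[[g]] <- m[, g]

  structure(list(biomarker = biomarker, arm = arm, patients = pat_ids,
                 draws = draws, rhat = rhat,
                 n_chains = mcmc$n_chains, n_draws = mcmc$n_draws,
                 seed = as.integer(seed), t_unit = "months"),
            class = "hier_posterior")
}

#' Construct a posterior object from explicit draws
#'
#' Low-level constructor used mainly to build degenerate or externally
#' supplied posteriors for the pseudo-trial machinery (e.g. a point-mass
#' posterior for deterministic checks).
#'
#' @param patients Character vector of patient ids.
#' @param alpha,beta,gamma,t_inflection Draw matrices (draws x patients) or
#'   vectors of length `patients` (recycled as a single draw).
#' @param sigma Vector of residual-SD draws (recycled to the draw count).
#' @param biomarker,arm Labels.
#' @return A `hier_posterior`.
#' @export
hier_posterior <- function(patients, alpha, beta, gamma, t_inflection,
                           sigma = 0, biomarker = "biomarker", arm = NULL) {
  as_mat <- function(x) {
    if (is.matrix(x)) {
      abort_if(ncol(x) != length(patients), "draw matrix has wrong width")
      colnames(x) <- patients
      x
    } else {
      matrix(rep(as.numeric(x), length.out = length(patients)), 1,
             dimnames = list(NULL, patients))
    }
  }
  draws <- list(alpha = as_mat(alpha), beta = as_mat(beta),
                gamma = as_mat(gamma), t_inflection = as_mat(t_inflection))
  ndraw <- max(vapply(draws, nrow, integer(1)))
  draws <- lapply(draws, function(m) {
    if (nrow(m) == ndraw) m else m[rep(seq_len(nrow(m)), length.out = ndraw), ,
                                   drop = FALSE]
  })
  draws$sigma <- rep(as.numeric(sigma), length.out = ndraw)
  structure(list(biomarker = biomarker, arm = arm, patients = patients,
                 draws = draws, rhat = NULL, n_chains = 1L, n_draws = ndraw,
                 seed = NA_integer_, t_unit = "months"),
            class = "hier_posterior")
}

#' @export
print.hier_posterior <- function(x, ...) {
  cat(sprintf("<hier_posterior> %s%s: %d patients, %d draws (%d chain%s)\n",
              x$biomarker, if (is.null(x$arm)) "" else paste0(" [", x$arm, "]"),
              length(x$patients), length(x$draws$sigma), x$n_chains,
              if (x$n_chains == 1) "" else "s"))
  if (!is.null(x$rhat) && !all(is.na(x$rhat))) {
    cat(sprintf("  group means: mu_beta %.3f, mu_gamma %.3f; max Rhat %.3f\n",
                mean(x$draws$mu_beta), mean(x$draws$mu_gamma),
                max(x$rhat, na.rm = TRUE)))
  }
  invisible(x)
}

#' Posterior slope table and arm comparison
#'
#' Summarises fitted arm-level posteriors of one biomarker into the slope
#' table layout used for reporting: posterior means (with SD and 95% credible
#' interval) of the group-level slope before (`beta`) and after (`gamma`) the
#' inflection point per arm, plus a Mann-Whitney test comparing patient-level
#' posterior-mean slopes between arms.
#'
#' @param standard,experimental `hier_posterior` objects for the two arms.
#' @return A list of class `slope_summary`: `table` (parameter, arm, mean, sd,
#'   q2.5, q97.5, rhat) and `comparison` (parameter, U, p_value).
#' @export
summarize_posterior <- function(standard, experimental) {
  abort_if(!inherits(standard, "hier_posterior") ||
             !inherits(experimental, "hier_posterior"),
           "both arms must be hier_posterior objects (missing arm?)")
  arms <- list(standard = standard, experimental = experimental)
  tab <- bind_rows(lapply(names(arms), function(a) {
    p <- arms[[a]]
    bind_rows(lapply(c(beta = "mu_beta", gamma = "mu_gamma"), function(g) {
      d <- p$draws[[g]]
      tibble(arm = a, mean = mean(d), sd = sd(d),
             q2.5 = unname(quantile(d, 0.025)),
             q97.5 = unname(quantile(d, 0.975)),
             rhat = if (is.null(p$rhat)) NA_real_ else unname(p$rhat[g]))
    }), .id = "parameter")
  }))
  cmp <- bind_rows(lapply(c("beta", "gamma"), function(par) {
    mw <- mann_whitney(colMeans(arms$experimental$draws[[par]]),
                       colMeans(arms$standard$draws[[par]]))
    tibble(parameter = par, U = mw$U, p_value = mw$p_value)
  }))
  structure(list(biomarker = standard$biomarker, table = tab, comparison = cmp),
            class = "slope_summary")
}

#' @export
print.slope_summary <- function(x, ...) {
  cat(sprintf("Group-level slopes, %s (log units per month)\n", x$biomarker))
  wide <- merge(
    x$table[x$table$arm == "experimental", c("parameter", "mean")],
    x$table[x$table$arm == "standard", c("parameter", "mean")],
    by = "parameter", suffixes = c("_experimental", "_standard"))
  wide <- merge(wide, x$comparison[, c("parameter", "p_value")], by = "parameter")
  print(as.data.frame(wide), row.names = FALSE, digits = 3)
  invisible(x)
}

#' Write posterior summaries as CSV
#'
#' @param summary A `slope_summary`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_slope_summary <- function(summary, path) {
  stopifnot(inherits(summary, "slope_summary"))
  tab <- summary$table
  tab$biomarker <- summary$biomarker
  tab <- left_join(tab, summary$comparison, by = "parameter")
  readr::write_csv(tab[, c("biomarker", "parameter", "arm", "mean", "sd",
                           "q2.5", "q97.5", "rhat", "p_value")], path)
  invisible(path)
}
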