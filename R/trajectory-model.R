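#' Piecewise-linear trajectory parameters
#'
#' One patient-biomarker trajectory on the natural-log concentration scale:
#' a pre-treatment level `alpha`, a slope `beta` before the inflection point,
#' a slope `gamma` after it, the inflection time `t_inflection` (months from
#' treatment start) and the residual SD `sigma`.
#'
#' @param alpha Pre-treatment log-concentration.
#' @param beta Slope before the inflection point (log units per month).
#' @param gamma Slope after the inflection point (log units per month).
#' @param t_inflection Inflection time in months; must be positive.
#' @param sigma Residual SD of log-concentration; `0` encodes a noiseless
#'   trajectory (rejected by [trajectory_log_likelihood()], which needs
#'   `sigma > 0`).
#' @return An object of class `piecewise_params`.
#' @export
piecewise_params <- function(alpha, beta, gamma, t_inflection, sigma = 0) {
  for (nm in c("alpha", "beta", "gamma", "t_inflection", "sigma")) {
    abort_if(!is_scalar_number(get(nm)), sprintf("`%s` must be a finite number", nm))
  }
  abort_if(t_inflection <= 0, "`t_inflection` must be > 0")
  abort_if(sigma < 0, "`sigma` must be >= 0")
  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 t_inflection = t_inflection, sigma = sigma),
            class = "piecewise_params")
}

#' @export
print.piecewise_params <- function(x, ...) {
  cat(sprintf(
    "<piecewise_params> alpha=%.4g beta=%.4g gamma=%.4g t_inflection=%.4g mo sigma=%.4g\n",
    x$alpha, x$beta, x$gamma, x$t_inflection, x$sigma))
  invisible(x)
}

#' Expected log-concentration of a piecewise-linear trajectory
#'
#' Evaluates `alpha + beta * min(t, t_inflection) + S * gamma * (t -
#' t_inflection)` with `S = 1` for `t > t_inflection` and `0` otherwise, which
#' is continuous in `t` and makes `beta`/`gamma` literally the slopes before
#' and after the inflection point. Times before treatment start (`t < 0`) are
#' clipped to the pre-treatment level `alpha`.
#'
#' @param params A [piecewise_params()] object.
#' @param t Time(s) in months from treatment start; vectorised.
#' @return Expected log-concentration at each `t`.
#' @export
evaluate_trajectory <- function(params, t) {
  stopifnot(inherits(params, "piecewise_params"), is.numeric(t))
  tc <- pmax(t, 0)
  params$alpha + params$beta * pmin(tc, params$t_inflection) +
    (tc > params$t_inflection) * params$gamma * (tc - params$t_inflection)
}

#' Gaussian log-likelihood of observed log-concentrations
#'
#' Sum of normal log-densities of the observed log-concentrations around the
#' piecewise-linear mean, with residual SD `params$sigma`.
#'
#' @param params A [piecewise_params()] object with `sigma > 0`.
#' @param t_months Observation times in months (pre-treatment times allowed).
#' @param log_concentration Observed natural-log concentrations.
#' @return Scalar log-likelihood.
#' @export
trajectory_log_likelihood <- function(params, t_months, log_concentration) {
  abort_if(params$sigma <= 0, "`sigma` must be > 0 for a likelihood")
  abort_if(length(t_months) == 0, "measurements must be non-empty")
  abort_if(length(t_months) != length(log_concentration),
           "times and values must have equal length")
  sum(dnorm(log_concentration,
            mean = evaluate_trajectory(params, t_months),
            sd = params$sigma, log = TRUE))
}

#' Ang1-Tie2 composite biomarker value
#'
#' The composite studied alongside Tie2 alone: the product of the Tie2
#' concentration and the log2-transformed Ang1 concentration.
#'
#' @param tie2_value Tie2 concentration(s).
#' @param ang1_value Ang1 concentration(s); must be positive.
#' @return `tie2_value * log2(ang1_value)`, vectorised.
#' @export
composite_ang1_tie2 <- function(tie2_value, ang1_value) {
  abort_if(any(!is.finite(ang1_value)) || any(ang1_value <= 0),
           "`ang1_value` must be positive")
  tie2_value * log2(ang1_value)
}

#' Add a time-matched Ang1 x Tie2 composite series to a cohort
#'
#' Creates a derived biomarker named `"Ang1xTie2"` from pairs of Tie2 and Ang1
#' measurements taken from the same patient at the same time.
#'
#' @param cohort A `biomarker_cohort`.
#' @param tie2,ang1 Names of the component biomarkers in the cohort.
#' @return The cohort with the composite rows appended.
#' @export
add_composite_ang1_tie2 <- function(cohort, tie2 = "Tie2", ang1 = "Ang1") {
  stopifnot(inherits(cohort, "biomarker_cohort"))
  s <- cohort$samples
  abort_if(!all(c(tie2, ang1) %in% s$biomarker),
           sprintf("cohort lacks biomarker(s): %s",
                   paste(setdiff(c(tie2, ang1), s$biomarker), collapse = ", ")))
  a <- s[s$biomarker == tie2, ]
  b <- s[s$biomarker == ang1, c("patient_id", "time_days", "concentration")]
  names(b)[3] <- ".ang1"
  m <- merge(as.data.frame(a), as.data.frame(b),
             by = c("patient_id", "time_days"))
  abort_if(nrow(m) == 0, "no time-matched Tie2/Ang1 pairs")
  m$concentration <- composite_ang1_tie2(m$concentration, m$.ang1)
  m$biomarker <- "Ang1xTie2"
  m$.ang1 <- NULL
  cohort$samples <- dplyr::bind_rows(s, as_tibble(m)) %>%
    arrange(.data$patient_id, .data$biomarker, .data$time_days)
  cohort
}
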