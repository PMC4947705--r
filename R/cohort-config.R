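#' Describe one biomarker for the synthetic-cohort generator
#'
#' A `biomarker_spec` holds the generative analogue of the piecewise-linear
#' trajectory model for one circulating biomarker: a log-normal pre-treatment
#' level, arm-specific slopes before and after an inflection point placed at a
#' fraction of each patient's progression-free survival (PFS), between-patient
#' slope spread, residual measurement noise, and a latent-factor block used to
#' induce cross-biomarker correlation.
#'
#' All concentrations are handled on the natural-log scale so that generated
#' concentrations are strictly positive; slopes are log-concentration units per
#' 30-day month. Within a `correlation_block`, baselines share a patient-level
#' latent factor and residuals at the same blood draw share a visit-level one,
#' both with the given loading; two biomarkers in one block therefore have an
#' implied correlation of `factor_loading^2` on each shared component (e.g.
#' residual correlation `factor_loading^2` when baselines are fixed).
#'
#' @param name Biomarker identifier (e.g. `"Tie2"`).
#' @param baseline_log_mean,baseline_log_sd Mean and between-patient SD of the
#'   natural-log pre-treatment concentration.
#' @param slope_before_mean,slope_after_mean Named numeric vectors with
#'   elements `standard` and `experimental`: group-mean slopes (log units per
#'   month) before and after the inflection point. An inflection-free arm is
#'   encoded by giving it equal before/after slopes.
#' @param slope_sd Between-patient SD of both slopes (log units per month).
#' @param inflection_fraction_mean,inflection_fraction_sd Mean (in (0,1)) and
#'   SD of the inflection time expressed as a fraction of the patient's PFS.
#' @param noise_sd Residual SD of log-concentration at a single measurement.
#' @param correlation_block Label of the latent-factor block.
#' @param factor_loading Loading on the shared within-block factor, in [0,1].
#' @return An object of class `biomarker_spec`.
#' @seealso [cohort_config()], [generate_cohort()]
#' @export
biomarker_spec <- function(name,
                           baseline_log_mean,
                           baseline_log_sd,
                           slope_before_mean,
                           slope_after_mean,
                           slope_sd,
                           inflection_fraction_mean = 0.6,
                           inflection_fraction_sd = 0.1,
                           noise_sd = 0.2,
                           correlation_block = name,
                           factor_loading = 0) {
  abort_if(!is.character(name) || length(name) != 1 || !nzchar(name),
           "`name` must be a non-empty string")
  slope_before_mean <- check_arm_vector(slope_before_mean, "slope_before_mean")
  slope_after_mean <- check_arm_vector(slope_after_mean, "slope_after_mean")
  abort_if(baseline_log_sd < 0 || slope_sd < 0 || noise_sd < 0 ||
             inflection_fraction_sd < 0,
           "standard deviations must be >= 0")
  abort_if(inflection_fraction_mean <= 0 || inflection_fraction_mean >= 1,
           "`inflection_fraction_mean` must lie in (0, 1)")
  abort_if(factor_loading < 0 || factor_loading > 1,
           "`factor_loading` must lie in [0, 1]")
  structure(
    list(name = name,
         baseline_log_mean = baseline_log_mean,
         baseline_log_sd = baseline_log_sd,
         slope_before_mean = slope_before_mean,
         slope_after_mean = slope_after_mean,
         slope_sd = slope_sd,
         inflection_fraction_mean = inflection_fraction_mean,
         inflection_fraction_sd = inflection_fraction_sd,
         noise_sd = noise_sd,
         correlation_block = correlation_block,
         factor_loading = factor_loading),
    class = "biomarker_spec")
}

check_arm_vector <- function(x, what) {
  if (length(x) == 1 && is.null(names(x))) {
    x <- c(standard = unname(x), experimental = unname(x))
  }
  abort_if(!all(c("standard", "experimental") %in% names(x)),
           sprintf("`%s` needs elements named 'standard' and 'experimental'", what))
  x[c("standard", "experimental")]
}

#' Default three-marker panel for the synthetic cohort
#'
#' Tie2, Ang1 and Ca125 specifications used as generator defaults. Slope means
#' follow the fitted group-level values reported for these markers (per-month,
#' log scale): Tie2 declines steeply then rebounds in the experimental arm and
#' is inflection-free in the standard arm; Ca125, a tumour-burden marker,
#' declines and rebounds identically in both arms; Ang1 shows a milder
#' bevacizumab-specific decline. Tie2 and Ang1 share a latent-factor block with
#' loading `sqrt(0.55)` so their implied residual correlation matches the
#' median correlation displayed in the biomarker networks.
#'
#' @return A named list of [biomarker_spec()] objects.
#' @export
default_biomarker_panel <- function() {
  loading <- sqrt(0.55)
  list(
    Tie2 = biomarker_spec(
      "Tie2",
      baseline_log_mean = log(20), baseline_log_sd = 0.3,
      slope_before_mean = c(standard = 0.2, experimental = -3.4),
      slope_after_mean = c(standard = 0.2, experimental = 0.9),
      slope_sd = 0.5, inflection_fraction_mean = 0.6,
      inflection_fraction_sd = 0.1, noise_sd = 0.2,
      correlation_block = "angio", factor_loading = loading),
    Ang1 = biomarker_spec(
      "Ang1",
      baseline_log_mean = log(30), baseline_log_sd = 0.4,
      slope_before_mean = c(standard = 0, experimental = -0.5),
      slope_after_mean = c(standard = 0, experimental = 0.3),
      slope_sd = 0.3, inflection_fraction_mean = 0.6,
      inflection_fraction_sd = 0.1, noise_sd = 0.2,
      correlation_block = "angio", factor_loading = loading),
    Ca125 = biomarker_spec(
      "Ca125",
      baseline_log_mean = log(300), baseline_log_sd = 1.0,
      slope_before_mean = c(standard = -4.4, experimental = -4.4),
      slope_after_mean = c(standard = 1.0, experimental = 0.9),
      slope_sd = 0.6, inflection_fraction_mean = 0.6,
      inflection_fraction_sd = 0.1, noise_sd = 0.3,
      correlation_block = "tumour", factor_loading = 0)
  )
}

#' Configuration of a synthetic two-arm trial cohort
#'
#' Bundles arm sizes, the biomarker panel, the PFS distribution, visit
#' missingness and the seed that makes the generated cohort reproducible.
#'
#' @param n_standard,n_experimental Patients per arm (default 44 / 48, the
#'   ICON7 translational-cohort arm sizes).
#' @param biomarkers Named list of [biomarker_spec()] objects.
#' @param pfs_distribution List describing the PFS distribution in days:
#'   `list(name = "lognormal", meanlog =, sdlog =)`,
#'   `list(name = "weibull", shape =, scale =)` or
#'   `list(name = "fixed", days =)`. Draws are floored at 60 days so every
#'   patient has on-treatment visits.
#' @param censor_rate Probability that a patient is censored (no progression
#'   sample, `progressed = FALSE`).
#' @param missing_rate Probability that a scheduled non-pre-treatment,
#'   non-progression visit is missing; missingness hits the whole blood draw,
#'   i.e. every biomarker at that visit.
#' @param seed Integer seed; the cohort is a deterministic function of the
#'   configuration.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_standard = 44,
                          n_experimental = 48,
                          biomarkers = default_biomarker_panel(),
                          pfs_distribution = list(name = "lognormal",
                                                  meanlog = log(540),
                                                  sdlog = 0.45),
                          censor_rate = 0.15,
                          missing_rate = 0.25,
                          seed = 1L) {
  abort_if(!is_scalar_number(n_standard) || !is_scalar_number(n_experimental) ||
             n_standard < 1 || n_experimental < 1,
           "arm sizes must be numbers >= 1")
  abort_if(length(biomarkers) < 1, "at least one biomarker is required")
  abort_if(!all(vapply(biomarkers, inherits, logical(1), "biomarker_spec")),
           "`biomarkers` must be a list of biomarker_spec objects")
  abort_if(!is_scalar_number(missing_rate) || missing_rate < 0 || missing_rate >= 1,
           "`missing_rate` must lie in [0, 1)")
  abort_if(!is_scalar_number(censor_rate) || censor_rate < 0 || censor_rate >= 1,
           "`censor_rate` must lie in [0, 1)")
  abort_if(!is.list(pfs_distribution) || is.null(pfs_distribution$name),
           "`pfs_distribution` must be a named list with a `name` element")
  names(biomarkers) <- vapply(biomarkers, `[[`, character(1), "name")
  structure(
    list(n_standard = as.integer(n_standard),
         n_experimental = as.integer(n_experimental),
         biomarkers = biomarkers,
         pfs_distribution = pfs_distribution,
         censor_rate = censor_rate,
         missing_rate = missing_rate,
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat(sprintf("  arms: %d standard / %d experimental\n",
              x$n_standard, x$n_experimental))
  cat(sprintf("  biomarkers: %s\n", paste(names(x$biomarkers), collapse = ", ")))
  cat(sprintf("  PFS: %s; censor_rate %.2f; missing_rate %.2f; seed %s\n",
              x$pfs_distribution$name, x$censor_rate, x$missing_rate,
              x$seed %||% "NULL"))
  invisible(x)
}

draw_pfs <- function(dist, n) {
  days <- switch(dist$name,
    lognormal = rlnorm(n, dist$meanlog, dist$sdlog),
    weibull = rweibull(n, dist$shape, dist$scale),
    fixed = rep(dist$days, n),
    stop("unknown pfs_distribution name: ", dist$name, call. = FALSE))
  pmax(round(days), 60)
}
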