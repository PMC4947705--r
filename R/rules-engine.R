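#' Nadir-elevation alarm rule
#'
#' A progression alarm fires when a biomarker rises by more than
#' `threshold_fraction` above its running nadir (the minimum concentration
#' observed so far). `threshold_fraction = 0.5` is the 50%-over-nadir rule
#' used for Tie2; `1.0` is the GCIG-style doubling rule for Ca125.
#'
#' @param biomarker Biomarker the rule monitors.
#' @param threshold_fraction Fractional elevation over the nadir that triggers
#'   the alarm; must be positive.
#' @param require_confirmation If `TRUE`, two consecutive exceedances are
#'   required and the alarm time is the second of them.
#' @return An object of class `alarm_rule`.
#' @export
alarm_rule <- function(biomarker, threshold_fraction = 0.5,
                       require_confirmation = FALSE) {
  abort_if(!is_scalar_number(threshold_fraction) || threshold_fraction <= 0,
           "`threshold_fraction` must be > 0")
  structure(list(biomarker = biomarker,
                 threshold_fraction = threshold_fraction,
                 require_confirmation = isTRUE(require_confirmation)),
            class = "alarm_rule")
}

#' Sequentially monitored biomarker series
#'
#' Ordered concentration measurements from treatment start for one patient,
#' as seen in clinic: strictly increasing times, positive concentrations.
#'
#' @param time_days Measurement times in days from treatment start.
#' @param concentration Positive concentrations.
#' @param pfs_days The patient's progression-free survival in days (NA if
#'   unknown).
#' @param progressed Whether the patient progressed.
#' @return An object of class `monitored_series`.
#' @export
monitored_series <- function(time_days, concentration, pfs_days = NA_real_,
                             progressed = NA) {
  abort_if(length(time_days) != length(concentration),
           "times and concentrations must have equal length")
  if (length(time_days) > 1) {
    abort_if(any(diff(time_days) <= 0), "times must be strictly increasing")
  }
  abort_if(any(concentration <= 0), "concentrations must be > 0")
  structure(list(time_days = as.numeric(time_days),
                 concentration = as.numeric(concentration),
                 pfs_days = pfs_days, progressed = progressed),
            class = "monitored_series")
}

# index of the first alarm in a value sequence, or NA. The nadir at step k is
# the minimum over steps <= k, so the first point can never alarm on itself.
alarm_index <- function(values, threshold_fraction, require_confirmation = FALSE) {
  if (length(values) == 0) return(NA_integer_)
  exceed <- values >= cummin(values) * (1 + threshold_fraction)
  if (require_confirmation) {
    exceed <- exceed & c(FALSE, exceed[-length(exceed)])
  }
  idx <- which(exceed)
  if (length(idx) == 0) NA_integer_ else idx[1]
}

#' First alarm time of a nadir-elevation rule
#'
#' Scans the series forward; at each step the nadir is the minimum
#' concentration observed up to and including that step, and the alarm fires
#' at the first step whose concentration reaches `nadir * (1 +
#' threshold_fraction)` (ties trigger: `>=`).
#'
#' @param series A [monitored_series()].
#' @param rule An [alarm_rule()], or a bare threshold fraction.
#' @return Alarm time in the series' time unit, or `NA` if never triggered.
#' @export
nadir_alarm <- function(series, rule = alarm_rule("any", 0.5)) {
  stopifnot(inherits(series, "monitored_series"))
  if (!inherits(rule, "alarm_rule")) rule <- alarm_rule("any", rule)
  idx <- alarm_index(series$concentration, rule$threshold_fraction,
                     rule$require_confirmation)
  if (is.na(idx)) NA_real_ else series$time_days[idx]
}

#' GCIG-style Ca125 progression alarm
#'
#' Biochemical Ca125 progression read as a doubling from the nadir, i.e. a
#' nadir-elevation rule with `threshold_fraction = 1`. The confirmation sample
#' of the clinical criteria is off by default (monthly monitored pseudo-trial
#' series would distort confirmation delays); set `require_confirmation =
#' TRUE` for the stricter variant.
#'
#' @inheritParams nadir_alarm
#' @param require_confirmation Require a second consecutive exceedance.
#' @return Alarm time or `NA`.
#' @export
gcig_ca125_alarm <- function(series, require_confirmation = FALSE) {
  nadir_alarm(series, alarm_rule("Ca125", 1.0, require_confirmation))
}

#' OR-combination of component alarms
#'
#' The combined rule alarms at the earliest component alarm; `NA` components
#' are ignored and all-`NA` yields `NA`.
#'
#' @param alarm_times Numeric vector of component alarm times (`NA` = no
#'   alarm).
#' @return Earliest alarm time or `NA`.
#' @export
combined_or_alarm <- function(alarm_times) {
  abort_if(length(alarm_times) == 0, "need at least one component alarm")
  if (all(is.na(alarm_times))) NA_real_ else min(alarm_times, na.rm = TRUE)
}

#' Cohort-level rule performance
#'
#' Summarises per-patient alarm outcomes into the prediction rate (% of
#' progressed patients with an alarm at or before progression) and the
#' prediction quality (mean %PFS time of the alarm among predicted patients,
#' with SD). Censored patients are excluded from the denominator.
#'
#' @param alarms Tibble/data.frame with columns `patient_id` and `alarm_time`
#'   (days; `NA` = no alarm).
#' @param patients Tibble with `patient_id`, `pfs_days`, `progressed`.
#' @param threshold_fraction Optional label carried into the output.
#' @return One-row tibble of class `rule_evaluation`: `threshold_fraction`,
#'   `prediction_rate`, `mean_prediction_time`, `sd_prediction_time`,
#'   `n_predicted`, `n_progressed`.
#' @export
evaluate_rule_over_cohort <- function(alarms, patients,
                                      threshold_fraction = NA_real_) {
  d <- left_join(as_tibble(alarms), as_tibble(patients), by = "patient_id")
  d <- d[d$progressed %in% TRUE, ]
  abort_if(nrow(d) == 0, "no progressed patients")
  predicted <- !is.na(d$alarm_time) & d$alarm_time <= d$pfs_days
  pct <- 100 * d$alarm_time[predicted] / d$pfs_days[predicted]
  out <- tibble(
    threshold_fraction = threshold_fraction,
    prediction_rate = 100 * mean(predicted),
    mean_prediction_time = if (any(predicted)) mean(pct) else NA_real_,
    sd_prediction_time = if (sum(predicted) > 1) sd(pct) else NA_real_,
    n_predicted = sum(predicted),
    n_progressed = nrow(d))
  class(out) <- c("rule_evaluation", class(out))
  out
}

#' Sweep alarm thresholds over a cohort of monitored series
#'
#' Applies the nadir-elevation rule at each threshold to every patient's
#' series and evaluates cohort performance, producing the (1 - prediction
#' rate) versus prediction-time trade-off curve.
#'
#' @param series_list Named list of [monitored_series()], names = patient ids.
#' @param patients Tibble with `patient_id`, `pfs_days`, `progressed`.
#' @param thresholds Positive threshold fractions to evaluate.
#' @param require_confirmation Passed to the rule.
#' @return Tibble with one [evaluate_rule_over_cohort()] row per threshold,
#'   of class `threshold_sweep`.
#' @export
threshold_sweep <- function(series_list, patients, thresholds = seq(0.1, 1.5, by = 0.1),
                            require_confirmation = FALSE) {
  abort_if(length(thresholds) == 0, "`thresholds` must be non-empty")
  abort_if(any(thresholds <= 0), "`threshold_fraction` must be > 0")
  abort_if(is.null(names(series_list)), "`series_list` must be named by patient id")
  out <- lapply(thresholds, function(th) {
    rule <- alarm_rule("sweep", th, require_confirmation)
    al <- tibble(
      patient_id = names(series_list),
      alarm_time = vapply(series_list, nadir_alarm, numeric(1), rule = rule))
    evaluate_rule_over_cohort(al, patients, threshold_fraction = th)
  })
  out <- bind_rows(out)
  class(out) <- c("threshold_sweep", class(out))
  out
}

#' Plot a threshold sweep as a prediction trade-off curve
#'
#' Plots 1 - prediction rate (missed patients, %) against mean %PFS time of
#' prediction; points near the top-left predict most patients early. The
#' 50%-over-nadir threshold is highlighted when present.
#'
#' @param x A `threshold_sweep`.
#' @param highlight Threshold to mark (default 0.5).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.threshold_sweep <- function(x, highlight = 0.5, ...) {
  miss <- 100 - x$prediction_rate
  graphics::plot(x$mean_prediction_time, miss, type = "b", pch = 16,
                 xlab = "mean %PFS time of prediction",
                 ylab = "patients without prediction (%)",
                 ylim = c(0, max(miss, 10)), ...)
  hit <- which(abs(x$threshold_fraction - highlight) < 1e-9)
  if (length(hit)) {
    graphics::points(x$mean_prediction_time[hit], miss[hit], pch = 21,
                     bg = "red", cex = 1.6)
  }
  invisible(x)
}
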