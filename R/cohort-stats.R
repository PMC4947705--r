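#' Mann-Whitney U test, exact for small groups
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test. With both group sizes at
#' most 8 the p-value is exact: the tie-free null distribution of U via
#' [stats::pwilcox()], or full enumeration of all group assignments when ties
#' are present (two-sided by distance of U from its null mean mn/2, exploiting
#' the symmetry of the permutation distribution). Larger samples use the
#' tie-corrected normal approximation (no continuity correction).
#'
#' @param x,y Numeric samples.
#' @param exact_max Largest group size for which the exact path is used.
#' @return List with `U` (the statistic for `x`: pairs where x > y, ties
#'   counting 1/2) and `p_value`.
#' @export
mann_whitney <- function(x, y, exact_max = 8) {
  m <- length(x); n <- length(y)
  abort_if(m == 0 || n == 0, "both groups must be non-empty")
  z <- c(x, y)
  rz <- rank(z)
  U <- sum(rz[seq_len(m)]) - m * (m + 1) / 2
  if (m <= exact_max && n <= exact_max) {
    if (!anyDuplicated(z)) {
      p <- 2 * min(pwilcox(U, m, n), 1 - pwilcox(U - 1, m, n))
    } else {
      sets <- combn(m + n, m)
      rsum <- colSums(matrix(rz[sets], nrow = m))
      Uperm <- rsum - m * (m + 1) / 2
      p <- mean(abs(Uperm - m * n / 2) >= abs(U - m * n / 2) - 1e-9)
    }
    p <- min(1, p)
  } else {
    p <- wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value
  }
  list(U = unname(U), p_value = unname(p))
}

#' Bonferroni-corrected significance threshold for the trajectory comparisons
#'
#' The family is every biomarker tested at every %PFS bin, so the per-test
#' threshold is `alpha / (n_biomarkers * n_bins)`; the default 15-marker panel
#' over ten 10%-PFS bins at family alpha 0.05 gives 1/3000, i.e. 0.0003 to one
#' significant figure.
#'
#' @param alpha Family-wise error rate.
#' @param n_biomarkers Biomarkers in the panel.
#' @param n_bins %PFS bins per biomarker.
#' @return The exact per-test threshold.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_biomarkers = 15, n_bins = 10) {
  abort_if(n_biomarkers < 1 || n_bins < 1, "counts must be >= 1")
  alpha / (n_biomarkers * n_bins)
}

#' Baseline-normalised %PFS series for one patient-biomarker
#'
#' Re-expresses a patient's measurements as natural-log ratios over the
#' baseline (the mean of the two pre-treatment concentrations, or the single
#' one available) against the percentage of the patient's PFS interval that
#' has elapsed. Pre-treatment draws collapse into one anchor point at
#' (%PFS = 0, log-ratio = 0); a sample taken at progression sits at %PFS =
#' 100.
#'
#' @param time_days Measurement times (days; negative = pre-treatment).
#' @param concentration Positive concentrations.
#' @param pfs_days The patient's PFS in days.
#' @return Tibble with `pct_pfs` and `log_ratio`, anchored at (0, 0).
#' @export
to_normalized_series <- function(time_days, concentration, pfs_days) {
  abort_if(!is_scalar_number(pfs_days) || pfs_days <= 0,
           "`pfs_days` must be positive")
  abort_if(any(concentration <= 0), "concentrations must be > 0")
  pre <- time_days < 0
  abort_if(!any(pre), "no pre-treatment sample")
  baseline <- mean(concentration[pre])
  on <- !pre
  tibble(pct_pfs = c(0, 100 * time_days[on] / pfs_days),
         log_ratio = c(0, log(concentration[on] / baseline)))
}

#' Per-%PFS-interval Mann-Whitney comparison of the arms
#'
#' Compares the two arms' baseline-normalised trajectories of one biomarker
#' in each 10% bin of PFS time. Each patient contributes the linear
#' interpolation of their own series at the bin midpoint (no extrapolation
#' beyond a patient's observed range); arms are compared per bin with the
#' two-sided Mann-Whitney test. The minimum p across bins is reported next to
#' the Bonferroni threshold for the full family (all biomarkers x all bins).
#'
#' @param normalized Tibble with columns `patient_id`, `arm`, `pct_pfs`,
#'   `log_ratio` (one biomarker; see [to_normalized_series()]).
#' @param interval_pct Bin width in %PFS (default 10).
#' @param alpha Family-wise error rate for the Bonferroni threshold.
#' @param n_biomarkers Panel size defining the test family (default 15).
#' @return Tibble of class `interval_comparison` (`bin_midpoint`,
#'   `n_standard`, `n_experimental`, `U`, `p_value`); attributes `min_p` and
#'   `bonferroni` carry the summary. Empty bins are skipped with a warning.
#' @export
interval_arm_comparison <- function(normalized, interval_pct = 10,
                                    alpha = 0.05, n_biomarkers = 15) {
  d <- as_tibble(normalized)
  abort_if(!all(c("patient_id", "arm", "pct_pfs", "log_ratio") %in% names(d)),
           "normalized data needs patient_id, arm, pct_pfs, log_ratio")
  n_bins <- ceiling(100 / interval_pct)
  mids <- interval_pct * (seq_len(n_bins) - 0.5)
  per_patient <- d %>% group_by(.data$patient_id, .data$arm) %>%
    summarise(value = list(stats::approx(.data$pct_pfs, .data$log_ratio,
                                         xout = mids, ties = mean)$y),
              .groups = "drop")
  vals <- do.call(rbind, per_patient$value)
  rows <- lapply(seq_along(mids), function(b) {
    xs <- vals[per_patient$arm == "standard", b]
    ys <- vals[per_patient$arm == "experimental", b]
    xs <- xs[!is.na(xs)]; ys <- ys[!is.na(ys)]
    if (length(xs) == 0 || length(ys) == 0) {
      warning(sprintf("bin at %.0f%% PFS has an empty arm; skipped", mids[b]),
              call. = FALSE)
      return(NULL)
    }
    mw <- mann_whitney(xs, ys)
    tibble(bin_midpoint = mids[b], n_standard = length(xs),
           n_experimental = length(ys), U = mw$U, p_value = mw$p_value)
  })
  out <- bind_rows(rows)
  abort_if(nrow(out) == 0, "both arms must be represented in at least one bin")
  structure(out, class = c("interval_comparison", class(out)),
            min_p = min(out$p_value),
            bonferroni = bonferroni_threshold(alpha, n_biomarkers, n_bins))
}

#' @export
print.interval_comparison <- function(x, ...) {
  cat(sprintf("min p = %.3g across %d bins; Bonferroni threshold %.3g (%.1g to 1 s.f.)\n",
              attr(x, "min_p"), nrow(x), attr(x, "bonferroni"),
              signif(attr(x, "bonferroni"), 1)))
  NextMethod()
}

#' Normalise a whole cohort's series for one biomarker
#'
#' Convenience wrapper applying [to_normalized_series()] per patient.
#'
#' @param cohort A `biomarker_cohort`.
#' @param biomarker Biomarker name.
#' @return Tibble with `patient_id`, `arm`, `pct_pfs`, `log_ratio`.
#' @export
normalize_cohort <- function(cohort, biomarker) {
  stopifnot(inherits(cohort, "biomarker_cohort"))
  s <- cohort$samples[cohort$samples$biomarker == biomarker, ]
  abort_if(nrow(s) == 0, sprintf("biomarker '%s' absent from dataset", biomarker))
  s <- left_join(s, cohort$patients[, c("patient_id", "pfs_days")],
                 by = "patient_id")
  s %>% group_by(.data$patient_id, .data$arm) %>%
    dplyr::reframe(to_normalized_series(.data$time_days, .data$concentration,
                                        .data$pfs_days[1]))
}

#' Compare biomarkers between complete response and stable disease
#'
#' Per-biomarker two-sided Mann-Whitney comparison of patients with complete
#' response (CR) against patients with stable disease (SD); partial
#' responders are excluded to sharpen the contrast. For Ca125 the comparison
#' additionally excludes patients whose pre-treatment Ca125 is below
#' 30 IU/l (tumour undetectable by GCIG criteria). Each patient contributes
#' the mean log concentration of their on-treatment, non-progression samples.
#'
#' @param cohort A `biomarker_cohort`.
#' @param responses Tibble with `patient_id` and `response` in
#'   `c("CR", "PR", "SD")`.
#' @param biomarkers Biomarkers to test (default: all in the cohort).
#' @param ca125_name Name of the Ca125 series in the cohort.
#' @param ca125_min Baseline Ca125 exclusion threshold (IU/l).
#' @return Tibble (`biomarker`, `n_cr`, `n_sd`, `U`, `p_value`).
#' @export
response_comparison <- function(cohort, responses, biomarkers = NULL,
                                ca125_name = "Ca125", ca125_min = 30) {
  stopifnot(inherits(cohort, "biomarker_cohort"))
  responses <- as_tibble(responses)
  abort_if(!all(c("patient_id", "response") %in% names(responses)),
           "`responses` needs patient_id and response")
  responses <- responses[responses$response %in% c("CR", "SD"), ]
  s <- cohort$samples
  biomarkers <- biomarkers %||% sort(unique(s$biomarker))
  # baseline Ca125 per patient, for the GCIG-undetectable exclusion
  ca_base <- s[s$biomarker == ca125_name & s$time_days < 0, ] %>%
    group_by(.data$patient_id) %>%
    summarise(baseline = mean(.data$concentration))
  rows <- lapply(biomarkers, function(bm) {
    v <- s[s$biomarker == bm & s$time_days >= 0 & !s$is_progression_sample, ] %>%
      group_by(.data$patient_id) %>%
      summarise(value = mean(log(.data$concentration)))
    v <- dplyr::inner_join(v, responses, by = "patient_id")
    if (bm == ca125_name) {
      keep <- ca_base$patient_id[ca_base$baseline >= ca125_min]
      v <- v[v$patient_id %in% keep, ]
    }
    cr <- v$value[v$response == "CR"]
    sd_ <- v$value[v$response == "SD"]
    abort_if(length(cr) == 0 || length(sd_) == 0,
             sprintf("empty CR or SD group for '%s' after exclusions", bm))
    mw <- mann_whitney(cr, sd_)
    tibble(biomarker = bm, n_cr = length(cr), n_sd = length(sd_),
           U = mw$U, p_value = mw$p_value)
  })
  bind_rows(rows)
}

#' Write an interval comparison as CSV
#'
#' Adds a summary row with the minimum p and the Bonferroni threshold.
#'
#' @param comparison An `interval_comparison`.
#' @param path Output CSV path.
#' @param biomarker Label for the biomarker column.
#' @return Invisibly, `path`.
#' @export
write_interval_comparison <- function(comparison, path, biomarker = NA_character_) {
  tab <- as_tibble(comparison)
  tab$biomarker <- biomarker
  tab$min_p <- attr(comparison, "min_p")
  tab$bonferroni_threshold <- attr(comparison, "bonferroni")
  readr::write_csv(tab, path)
  invisible(path)
}
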