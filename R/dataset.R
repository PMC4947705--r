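SAMPLE_COLUMNS <- c("patient_id", "arm", "biomarker", "time_days",
                    "concentration", "visit_label", "is_progression_sample")
PATIENT_COLUMNS <- c("patient_id", "arm", "pfs_days", "progressed")

new_biomarker_cohort <- function(samples, patients, config = NULL) {
  samples <- as_tibble(samples)[, SAMPLE_COLUMNS]
  patients <- as_tibble(patients)[, PATIENT_COLUMNS]
  samples <- arrange(samples, .data$patient_id, .data$biomarker, .data$time_days)
  out <- structure(list(samples = samples, patients = patients,
                        config = config),
                   class = "biomarker_cohort")
  validate_cohort(out)
}

validate_cohort <- function(cohort) {
  s <- cohort$samples
  p <- cohort$patients
  abort_if(any(!is.finite(s$concentration) | s$concentration <= 0),
           "concentrations must be positive")
  abort_if(anyDuplicated(s[, c("patient_id", "biomarker", "time_days")]) > 0,
           "duplicate (patient_id, biomarker, time_days) measurement")
  abort_if(!all(s$patient_id %in% p$patient_id),
           "samples reference unknown patient_id")
  abort_if(!all(s$arm %in% c("standard", "experimental")),
           "arm must be 'standard' or 'experimental'")
  pre <- s %>% group_by(.data$patient_id, .data$biomarker) %>%
    summarise(n_pre = sum(.data$time_days < 0),
              n_prog = sum(.data$is_progression_sample), .groups = "drop")
  abort_if(any(pre$n_pre < 1),
           "each patient needs >= 1 pre-treatment record per biomarker")
  abort_if(any(pre$n_prog > 1),
           "at most one progression sample per patient-biomarker")
  cohort
}

#' @export
print.biomarker_cohort <- function(x, ...) {
  per_arm <- table(x$patients$arm)
  cat("<biomarker_cohort>\n")
  cat(sprintf("  %d patients (%s), %d measurements, biomarkers: %s\n",
              nrow(x$patients),
              paste(sprintf("%d %s", per_arm, names(per_arm)), collapse = " / "),
              nrow(x$samples),
              paste(unique(x$samples$biomarker), collapse = ", ")))
  spp <- x$samples %>% distinct(.data$patient_id, .data$time_days) %>%
    group_by(.data$patient_id) %>% summarise(k = n())
  cat(sprintf("  blood draws per patient: %.1f +/- %.1f; %d progressed\n",
              mean(spp$k), sd(spp$k), sum(x$patients$progressed)))
  invisible(x)
}

#' Write a cohort to a pair of CSV files
#'
#' Long-format measurements go to `<stem>_samples.csv` and patient metadata to
#' `<stem>_patients.csv`.
#'
#' @param cohort A `biomarker_cohort`.
#' @param stem Path stem (directory must exist).
#' @return Invisibly, the two file paths.
#' @export
write_cohort <- function(cohort, stem) {
  stopifnot(inherits(cohort, "biomarker_cohort"))
  paths <- paste0(stem, c("_samples.csv", "_patients.csv"))
  readr::write_csv(cohort$samples, paths[1])
  readr::write_csv(cohort$patients, paths[2])
  invisible(paths)
}

#' Read and validate a cohort from CSV files
#'
#' Expects the two-file layout written by [write_cohort()]. The dataset
#' invariants (positive concentrations, no duplicate measurements, at least
#' one pre-treatment record per patient-biomarker, at most one progression
#' sample) are enforced; a short load summary is printed unless `quiet`.
#'
#' @param samples_path,patients_path CSV paths.
#' @param quiet Suppress the load summary.
#' @return A `biomarker_cohort`.
#' @export
read_cohort <- function(samples_path, patients_path, quiet = FALSE) {
  s <- readr::read_csv(samples_path, show_col_types = FALSE, progress = FALSE)
  p <- readr::read_csv(patients_path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(SAMPLE_COLUMNS, names(s))
  abort_if(length(miss) > 0,
           sprintf("samples file missing column(s): %s",
                   paste(miss, collapse = ", ")))
  miss <- setdiff(PATIENT_COLUMNS, names(p))
  abort_if(length(miss) > 0,
           sprintf("patients file missing column(s): %s",
                   paste(miss, collapse = ", ")))
  out <- new_biomarker_cohort(s, p)
  if (!quiet) print(out)
  out
}

#' Extract one patient-biomarker monitored series
#'
#' On-treatment measurements (`time_days >= 0`, including the progression
#' sample) of one biomarker for one patient, as a [monitored_series()] ready
#' for the alarm rules.
#'
#' @param cohort A `biomarker_cohort`.
#' @param biomarker Biomarker name.
#' @param patient_id Patient identifier.
#' @return A `monitored_series`.
#' @export
extract_series <- function(cohort, biomarker, patient_id) {
  stopifnot(inherits(cohort, "biomarker_cohort"))
  s <- cohort$samples
  s <- s[s$biomarker == biomarker & s$patient_id == patient_id &
           s$time_days >= 0, ]
  p <- cohort$patients[cohort$patients$patient_id == patient_id, ]
  abort_if(nrow(p) == 0, sprintf("unknown patient '%s'", patient_id))
  monitored_series(s$time_days, s$concentration,
                   pfs_days = p$pfs_days, progressed = p$progressed)
}
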