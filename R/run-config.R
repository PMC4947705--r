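#' Read a pipeline run configuration
#'
#' Reads a YAML or JSON configuration and materialises the typed
#' sub-configurations: the synthetic-cohort block (`cohort:`), MCMC settings
#' (`mcmc:`), pseudo-trial settings (`pseudo_trial:`), alarm thresholds
#' (`rules:`) and the biomarker panel. Any omitted block falls back to the
#' package defaults. A top-level `seed` seeds every stochastic stage unless a
#' block carries its own.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @param seed Optional seed overriding the file's.
#' @return A list of class `run_config` with elements `cohort`
#'   ([cohort_config()]), `mcmc` ([mcmc_settings()]), `pseudo_trial`
#'   ([pseudo_trial_config()]), `rules`, `biomarker`, `seed`, `raw`.
#' @export
read_run_config <- function(path, seed = NULL) {
  abort_if(!file.exists(path), sprintf("config file not found: %s", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  seed <- as.integer(seed %||% raw$seed %||% 1L)
  cc <- raw$cohort %||% list()
  panel <- default_biomarker_panel()
  if (!is.null(cc$biomarkers)) {
    panel <- lapply(cc$biomarkers, function(b) {
      b$slope_before_mean <- unlist(b$slope_before_mean)
      b$slope_after_mean <- unlist(b$slope_after_mean)
      do.call(biomarker_spec, b)
    })
  }
  cohort <- cohort_config(
    n_standard = cc$n_standard %||% 44,
    n_experimental = cc$n_experimental %||% 48,
    biomarkers = panel,
    pfs_distribution = cc$pfs_distribution %||%
      list(name = "lognormal", meanlog = log(540), sdlog = 0.45),
    censor_rate = cc$censor_rate %||% 0.15,
    missing_rate = cc$missing_rate %||% 0.25,
    seed = cc$seed %||% seed)
  mc <- raw$mcmc %||% list()
  mcmc <- mcmc_settings(n_chains = mc$n_chains %||% 2,
                        n_adapt = mc$n_adapt %||% 500,
                        n_warmup = mc$n_warmup %||% 500,
                        n_draws = mc$n_draws %||% 1000)
  pt <- raw$pseudo_trial %||% list()
  pseudo <- pseudo_trial_config(
    n_replicates = pt$n_replicates %||% 5000,
    visit_interval_days = pt$visit_interval_days %||% 30,
    visit_jitter_days = pt$visit_jitter_days %||% 5,
    seed = pt$seed %||% seed,
    aggregate = pt$aggregate %||% "mean")
  structure(list(cohort = cohort, mcmc = mcmc, pseudo_trial = pseudo,
                 rules = raw$rules %||% list(Tie2 = 0.5, Ca125 = 1.0),
                 biomarker = raw$biomarker %||% "Tie2",
                 seed = seed, path = path, raw = raw),
            class = "run_config")
}

#' Write a JSON run manifest
#'
#' Records what is needed to re-run a stage: the subcommand, seed, config
#' file hash, and package/R versions. Deliberately timestamp-free so repeated
#' runs of a deterministic stage produce byte-identical artifacts.
#'
#' @param stage Stage name.
#' @param config A `run_config`.
#' @param out_dir Output directory.
#' @param extra Optional named list merged into the manifest.
#' @return Invisibly, the manifest path.
#' @export
write_run_manifest <- function(stage, config, out_dir, extra = list()) {
  manifest <- c(list(
    stage = stage,
    seed = config$seed,
    config_path = config$path,
    config_md5 = unname(tools::md5sum(config$path)),
    package = "angiotraj",
    package_version = as.character(utils::packageVersion("angiotraj")),
    r_version = paste(R.version$major, R.version$minor, sep = ".")),
    extra)
  path <- file.path(out_dir, sprintf("manifest_%s.json", stage))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
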