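#' Select a sample-by-biomarker matrix for network analysis
#'
#' Builds the measurement matrix underlying the biomarker correlation
#' networks. The `"pretreatment"` subset takes all pre-treatment draws of both
#' arms; the on-treatment subsets take one arm's post-treatment draws and
#' exclude progression samples, which would confound treatment effect with
#' progression biology. Rows are time-matched blood draws (one patient-visit)
#' with every panel biomarker present; values are natural-log concentrations
#' by default.
#'
#' @param cohort A `biomarker_cohort`.
#' @param subset One of `"pretreatment"`, `"standard_on_treatment"`,
#'   `"experimental_on_treatment"`.
#' @param biomarkers Panel to use (default: all biomarkers in the cohort).
#' @param log Return log concentrations (default `TRUE`).
#' @param collapse_patients Average each patient's qualifying draws into one
#'   row per patient, instead of pooling all draws.
#' @return Numeric matrix, rows = samples (or patients), columns = biomarkers.
#' @export
select_samples <- function(cohort,
                           subset = c("pretreatment", "standard_on_treatment",
                                      "experimental_on_treatment"),
                           biomarkers = NULL, log = TRUE,
                           collapse_patients = FALSE) {
  stopifnot(inherits(cohort, "biomarker_cohort"))
  subset <- match.arg(subset)
  s <- cohort$samples
  biomarkers <- biomarkers %||% sort(unique(s$biomarker))
  s <- s[s$biomarker %in% biomarkers, ]
  s <- switch(subset,
    pretreatment = s[s$time_days < 0, ],
    standard_on_treatment =
      s[s$arm == "standard" & s$time_days >= 0 & !s$is_progression_sample, ],
    experimental_on_treatment =
      s[s$arm == "experimental" & s$time_days >= 0 & !s$is_progression_sample, ])
  abort_if(nrow(s) == 0, sprintf("no samples left for subset '%s'", subset))
  s$value <- if (log) base::log(s$concentration) else s$concentration
  wide <- tidyr::pivot_wider(
    s[, c("patient_id", "time_days", "biomarker", "value")],
    names_from = "biomarker", values_from = "value")
  wide <- wide[stats::complete.cases(wide[, biomarkers]), ]
  abort_if(nrow(wide) == 0, sprintf("no complete samples for subset '%s'", subset))
  if (collapse_patients) {
    wide <- wide %>% group_by(.data$patient_id) %>%
      summarise(dplyr::across(dplyr::all_of(biomarkers), mean))
  }
  m <- as.matrix(wide[, biomarkers])
  rownames(m) <- if (collapse_patients) wide$patient_id else
    paste0(wide$patient_id, "@", wide$time_days)
  m
}

new_correlation_network <- function(weights, method, subset_label = NA_character_,
                                    shrinkage = NA_real_) {
  structure(list(nodes = colnames(weights), weights = weights, method = method,
                 subset_label = subset_label, shrinkage = shrinkage),
            class = "correlation_network")
}

#' @export
print.correlation_network <- function(x, ...) {
  off <- x$weights[upper.tri(x$weights)]
  cat(sprintf("<correlation_network> %s%s: %d nodes; |r| max %.2f, median %.2f%s\n",
              x$method,
              if (is.na(x$subset_label)) "" else paste0(" (", x$subset_label, ")"),
              length(x$nodes), max(abs(off)), median(abs(off)),
              if (is.na(x$shrinkage)) "" else
                sprintf("; shrinkage %.3f", x$shrinkage)))
  invisible(x)
}

#' Pearson correlation network
#'
#' Pairwise Pearson correlations between biomarker columns of a measurement
#' matrix (typically log concentrations from [select_samples()]).
#'
#' @param x Numeric matrix, rows = samples, columns = biomarkers; at least 3
#'   rows and no constant column.
#' @param subset_label Optional label carried into the network.
#' @return A `correlation_network` with the correlation matrix as weights.
#' @export
pearson_network <- function(x, subset_label = NA_character_) {
  x <- as.matrix(x)
  abort_if(nrow(x) < 3, "need >= 3 samples")
  sds <- apply(x, 2, sd)
  abort_if(any(sds == 0),
           sprintf("constant column(s): %s",
                   paste(colnames(x)[sds == 0], collapse = ", ")))
  new_correlation_network(cor(x), "pearson", subset_label)
}

#' Partial correlations from a correlation matrix
#'
#' Inverts the correlation matrix and standardises the precision matrix:
#' `pc[i,j] = -P[i,j] / sqrt(P[i,i] * P[j,j])`, the correlation of each pair
#' given all remaining variables. The diagonal is set to 1.
#'
#' @param R Symmetric positive-definite correlation matrix.
#' @return Matrix of partial correlations.
#' @export
partial_correlation <- function(R) {
  P <- tryCatch(solve(R),
                error = function(e) stop("correlation matrix is singular; ",
                                         "use shrinkage", call. = FALSE))
  pc <- -P / sqrt(diag(P) %o% diag(P))
  diag(pc) <- 1
  dimnames(pc) <- dimnames(R)
  pc
}

# Ledoit-Wolf-style shrinkage of the correlation matrix toward the identity:
# off-diagonal correlations are damped by 1 - lambda, with lambda the
# Schafer-Strimmer estimate sum(var(r_ij)) / sum(r_ij^2) from the empirical
# variance of the pairwise correlations.
shrink_correlation <- function(x) {
  n <- nrow(x)
  xs <- scale(x)  # sd denominator n-1
  w <- array(0, dim = c(n, ncol(x), ncol(x)))
  for (k in seq_len(n)) w[k, , ] <- tcrossprod(xs[k, ])
  r <- apply(w, c(2, 3), mean) * n / (n - 1)
  var_r <- apply(w, c(2, 3), stats::var) * n / (n - 1)^2
  off <- upper.tri(r)
  lambda <- min(1, max(0, sum(var_r[off]) / sum(r[off]^2)))
  R <- (1 - lambda) * r
  diag(R) <- 1
  list(R = R, lambda = lambda)
}

#' Partial correlation network
#'
#' Partial correlations between biomarkers from the inverse (precision)
#' matrix of their correlation matrix. When there are at least as many
#' biomarkers as samples (or the plain inverse is singular), the correlation
#' matrix is first shrunk toward the identity (Ledoit-Wolf style, data-driven
#' intensity), which the small-n/many-marker setting of biomarker panels
#' routinely needs.
#'
#' @inheritParams pearson_network
#' @param shrink `"auto"` (shrink when columns >= rows), `TRUE` or `FALSE`.
#' @return A `correlation_network` with partial correlations as weights.
#' @export
partial_correlation_network <- function(x, subset_label = NA_character_,
                                        shrink = "auto") {
  x <- as.matrix(x)
  abort_if(nrow(x) < 3, "need >= 3 samples")
  use_shrink <- isTRUE(shrink) ||
    (identical(shrink, "auto") && ncol(x) >= nrow(x))
  if (use_shrink) {
    sh <- shrink_correlation(x)
    new_correlation_network(partial_correlation(sh$R), "partial",
                            subset_label, shrinkage = sh$lambda)
  } else {
    new_correlation_network(partial_correlation(cor(x)), "partial",
                            subset_label)
  }
}

#' Threshold network edges for display
#'
#' Keeps edges with `|weight| >= cutoff` (0.3 by default, the display cut-off
#' of the correlation-network figures), tags their sign, and reports the
#' maximum and median displayed |weight|.
#'
#' @param network A `correlation_network`.
#' @param cutoff Absolute-weight display threshold.
#' @return Tibble of class `edge_table` (`node_a`, `node_b`, `weight`,
#'   `sign`, `method`, `subset_label`), sorted by |weight| descending with
#'   `node_a < node_b`; attributes `max_abs`, `median_abs` summarise the
#'   displayed edges.
#' @export
threshold_edges <- function(network, cutoff = 0.3) {
  stopifnot(inherits(network, "correlation_network"))
  W <- network$weights
  idx <- which(upper.tri(W), arr.ind = TRUE)
  a <- network$nodes[idx[, 1]]
  b <- network$nodes[idx[, 2]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  e <- tibble(node_a = a, node_b = b, weight = W[idx])
  e <- e[abs(e$weight) >= cutoff, ]
  e <- e[order(-abs(e$weight), e$node_a, e$node_b), ]
  e$sign <- ifelse(e$weight >= 0, "positive", "negative")
  e$method <- network$method
  e$subset_label <- network$subset_label
  structure(e, class = c("edge_table", class(e)),
            max_abs = if (nrow(e)) max(abs(e$weight)) else NA_real_,
            median_abs = if (nrow(e)) median(abs(e$weight)) else NA_real_)
}

#' @export
print.edge_table <- function(x, ...) {
  cat(sprintf("%d edge(s) displayed; max |r| %.2f, median |r| %.2f\n",
              nrow(x), attr(x, "max_abs"), attr(x, "median_abs")))
  NextMethod()
}

#' Write an edge table as TSV
#'
#' @param edges An `edge_table` from [threshold_edges()].
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_edges <- function(edges, path) {
  readr::write_tsv(as_tibble(edges), path)
  invisible(path)
}
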