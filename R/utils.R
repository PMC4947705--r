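`%||%` <- function(x, y) if (is.null(x)) y else x

# run code under a temporary RNG seed without disturbing the caller's stream;
# seed = NULL uses the ambient RNG
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

# derive a stream-specific child seed that stays inside .Machine$integer.max
child_seed <- function(seed, ...) {
  if (is.null(seed)) return(NULL)
  idx <- c(...)
  s <- as.double(seed)
  for (k in seq_along(idx)) s <- (s * 48271 + as.double(idx[k])) %% 2147483647
  as.integer(s)
}

abort_if <- function(cond, msg, call. = FALSE) {
  if (isTRUE(cond)) stop(msg, call. = call.)
  invisible(NULL)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
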