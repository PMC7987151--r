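#' @keywords internal
"_PACKAGE"

#' Derive a deterministic sub-seed from a master seed
#'
#' Mixes a master seed with one or more integer counters into a new seed in
#' the 32-bit range. Used throughout the package to give each stage (group
#' sampling, per-item tie-breaking, demographics) its own reproducible RNG
#' stream, so results do not depend on the order in which stages or items
#' are processed. The mixing constants are arbitrary odd primes.
#'
#' @param seed Master integer seed.
#' @param ... Integer counters identifying the sub-stream.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483647
  for (k in seq_along(idx)) {
    s <- (s * 48271 + as.double(idx[k]) * 16807 + k * 8191) %% 2147483647
  }
  as.integer(s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_cs <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_prob_vector <- function(p, tol = 1e-9, what = "p") {
  if (any(!is.finite(p)) || any(p < 0))
    stop_cs("'%s' must be a vector of finite non-negative probabilities", what)
  if (abs(sum(p) - 1) > tol)
    stop_cs("'%s' must sum to 1 (got %.15f)", what, sum(p))
  invisible(p)
}
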