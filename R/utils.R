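#' Seed the R RNG for a stochastic operation
#'
#' All stochastic functions in the package take an explicit integer seed and
#' route it through this helper, so every result is reproducible from the
#' seeds recorded in configs and logs. A `NULL` seed leaves the current RNG
#' stream untouched.
#' @keywords internal
local_rng <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

#' Derive a stage seed from a master seed
#'
#' Deterministic fan-out of one master seed into per-stage / per-subject
#' seeds via a multiplicative congruential mix, kept inside the 32-bit
#' integer range.
#'
#' @param master master integer seed.
#' @param ... integer stage/indices mixed into the derived seed.
#' @return a positive integer seed below 2^31.
#' @export
derive_seed <- function(master, ...) {
  s <- as.double(master) %% 2147483647
  for (x in c(...)) {
    s <- (s * 69069 + as.double(x) + 1) %% 2147483647
  }
  as.integer(max(1, s))
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
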