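`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a reproducible sub-seed from a parent seed
#'
#' Mixes a parent seed with one or more integer indices through a
#' Lehmer-style multiplicative congruence so that nested simulations
#' (subjects, sessions, records) each get an independent, reproducible
#' stream.  The result always fits in a signed 32-bit integer.
#'
#' @param seed parent integer seed.
#' @param ... integer indices identifying the sub-stream.
#' @return a single integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483647
  for (k in idx) {
    s <- (s * 48271 + as.double(k) + 1) %% 2147483647
  }
  as.integer(s)
}

# Stop with a consistent message prefix.
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
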