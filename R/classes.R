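#' Construct an ECG signal object
#'
#' A thin container for a raw single-lead ECG sample sequence.  Samples are
#' unit-agnostic (ADC units or millivolts) and are never filtered, detrended
#' or rescaled by this package: the reduced-binary-pattern encoding works on
#' the raw signal directly.
#'
#' @param samples numeric vector of amplitudes, length at least 2.
#' @param fs sampling rate in Hz, strictly positive.
#' @param subject_id optional opaque subject label.
#' @param record_id optional opaque record label.
#' @param timestamp optional acquisition date/time (`Date` or `POSIXct`),
#'   used to order records in the long-term evolving protocol.
#' @return an object of class `ecg_signal` with fields `samples`, `fs`,
#'   `subject_id`, `record_id`, `timestamp`.
#' @examples
#' sig <- ecg_signal(sin(seq(0, 10, by = 0.01)), fs = 100)
#' length(sig$samples)
#' @export
ecg_signal <- function(samples, fs, subject_id = NULL, record_id = NULL,
                       timestamp = NULL) {
  samples <- as.numeric(samples)
  if (length(samples) < 2L) {
    abort("ecg_signal: need at least 2 samples, got %d", length(samples))
  }
  if (anyNA(samples)) abort("ecg_signal: samples contain NA")
  if (!is.numeric(fs) || length(fs) != 1L || is.na(fs) || fs <= 0) {
    abort("ecg_signal: fs must be a single positive number")
  }
  structure(
    list(samples = samples, fs = as.numeric(fs), subject_id = subject_id,
         record_id = record_id, timestamp = timestamp),
    class = "ecg_signal"
  )
}

#' @export
print.ecg_signal <- function(x, ...) {
  cat(sprintf("<ecg_signal> %d samples @ %g Hz (%.1f s)",
              length(x$samples), x$fs, length(x$samples) / x$fs))
  if (!is.null(x$subject_id)) cat(" subject:", x$subject_id)
  if (!is.null(x$record_id)) cat(" record:", x$record_id)
  cat("\n")
  invisible(x)
}

#' Reduced-binary-pattern parameters
#'
#' Bundles the algorithm knobs: word length `m`, interval scaling factor
#' `alpha`, amplitude granularity `beta` and (for the evolving model) the
#' blending weight `gamma`.
#'
#' * `m` — number of bits per word; the word alphabet has `2^m` symbols.
#'   Larger `m` gives a finer pattern vocabulary but needs longer segments
#'   to populate the histogram; `m = 8` is the working default.
#' * `alpha` — stride of the pairwise comparison.  `alpha = 1` compares
#'   consecutive samples; `alpha > 1` compares samples `2*alpha` apart on an
#'   `alpha`-spaced grid, acting as an effective down-sampler.
#' * `beta` — amplitude threshold: a rise must exceed `beta` (same units as
#'   the signal) to emit a 1, which suppresses small noise-driven rises.
#' * `gamma` — weight of the newest record when blending frequencies into
#'   an evolving model; `0` never updates, `1` replaces outright.
#'
#' @param m word length in bits, integer in `[1, 16]`.
#' @param alpha interval scaling factor, integer `>= 1`.
#' @param beta amplitude granularity, `>= 0`.
#' @param gamma evolving blend weight in `[0, 1]`.
#' @return an object of class `rbp_params`.
#' @examples
#' rbp_params(m = 8, alpha = 15, beta = 1)
#' @export
rbp_params <- function(m = 8L, alpha = 1L, beta = 0, gamma = 0.5) {
  m <- as.integer(m)
  if (is.na(m) || m < 1L || m > 16L) {
    abort("rbp_params: m must be an integer in [1, 16], got %s", m)
  }
  alpha <- as.integer(alpha)
  if (is.na(alpha) || alpha < 1L) {
    abort("rbp_params: alpha must be an integer >= 1, got %s", alpha)
  }
  if (!is.numeric(beta) || length(beta) != 1L || is.na(beta) || beta < 0) {
    abort("rbp_params: beta must be a single number >= 0")
  }
  if (!is.numeric(gamma) || length(gamma) != 1L || is.na(gamma) ||
      gamma < 0 || gamma > 1) {
    abort("rbp_params: gamma must lie in [0, 1]")
  }
  structure(list(m = m, alpha = alpha, beta = as.numeric(beta),
                 gamma = as.numeric(gamma)),
            class = "rbp_params")
}

#' @export
print.rbp_params <- function(x, ...) {
  cat(sprintf("<rbp_params> m=%d alpha=%d beta=%g gamma=%g\n",
              x$m, x$alpha, x$beta, x$gamma))
  invisible(x)
}
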