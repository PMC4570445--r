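# Seeded multi-subject synthetic single-lead ECG.  Each beat is a sum of
# five Gaussian bumps (P, Q, R, S, T) placed at subject-specific fractions
# of the beat period; beat-to-beat interval jitter, a slow respiratory
# baseline wander and additive broadband noise complete the stated world.
# Output is quantized to integer ADC units (200 units/mV, offset 1024),
# mirroring 11/12-bit PhysioNet-style storage, so the amplitude threshold
# beta is expressed in ADC units as it is for real records.  The broadband
# noise level is that of a clean resting recording (a few microvolts to
# ~10 uV), which together with quantization is the regime the amplitude
# threshold beta = 1 ADC unit is meant to suppress; the wander gives
# baseline regions locally consistent slope signs, as in real records.

# Documented sampling ranges for subject templates.  Amplitudes in mV,
# centers/widths as fractions of the beat period, heart rate in bpm,
# interval jitter in seconds, noise/wander amplitudes in mV, wander
# frequency in Hz.
TEMPLATE_RANGES <- list(
  P = list(amp = c(0.05, 0.25), center = c(0.10, 0.20), width = c(0.020, 0.050)),
  Q = list(amp = c(-0.20, -0.05), center = c(0.32, 0.38), width = c(0.008, 0.020)),
  R = list(amp = c(0.80, 1.80), center = c(0.40, 0.44), width = c(0.008, 0.020)),
  S = list(amp = c(-0.45, -0.10), center = c(0.46, 0.52), width = c(0.008, 0.020)),
  T = list(amp = c(0.15, 0.55), center = c(0.60, 0.75), width = c(0.040, 0.080)),
  hr_bpm = c(55, 95),
  hrv_s = c(0.01, 0.05),
  # broadband noise depends on the acquisition setting: ambulatory
  # (Holter-style) recordings carry visibly more motion/muscle noise than
  # supine resting recordings
  noise_mv = list(ambulatory = c(0.010, 0.030), resting = c(0.003, 0.012)),
  wander_mv = c(0.03, 0.10),
  wander_hz = c(0.15, 0.40)
)

ADC_GAIN <- 200    # ADC units per mV
ADC_ZERO <- 1024   # baseline offset, ADC units

new_subject_template <- function(waves, hr_bpm, hrv_s, noise_mv,
                                 wander_mv = 0, wander_hz = 0.25,
                                 drift_rate = 0) {
  stopifnot(all(waves$width > 0), hr_bpm > 30, hr_bpm < 220, noise_mv >= 0,
            wander_mv >= 0)
  structure(list(waves = waves, hr_bpm = hr_bpm, hrv_s = hrv_s,
                 noise_mv = noise_mv, wander_mv = wander_mv,
                 wander_hz = wander_hz, drift_rate = drift_rate),
            class = "subject_template")
}

#' Draw a random subject template
#'
#' Samples per-wave amplitudes, centers and widths, a mean heart rate,
#' beat-to-beat interval jitter, baseline-wander parameters and a noise
#' level uniformly from the documented ranges (`TEMPLATE_RANGES` in the
#' package source).  The same seed always yields the same template.
#'
#' @param seed integer seed.
#' @param scenario acquisition setting controlling the broadband noise
#'   range: `"ambulatory"` (Holter-style, noisier; the default) or
#'   `"resting"` (clean supine recording, as in long-term enrolment
#'   sessions).
#' @return an object of class `subject_template` with fields `waves`
#'   (data frame with columns wave/amp/center/width), `hr_bpm`, `hrv_s`,
#'   `noise_mv`, `wander_mv`, `wander_hz`, `drift_rate`.
#' @export
sample_subject <- function(seed, scenario = c("ambulatory", "resting")) {
  scenario <- match.arg(scenario)
  noise_range <- TEMPLATE_RANGES$noise_mv[[scenario]]
  withr::with_seed(as.integer(seed), {
    wn <- c("P", "Q", "R", "S", "T")
    waves <- data.frame(
      wave = wn,
      amp = vapply(wn, function(w) stats::runif(1, TEMPLATE_RANGES[[w]]$amp[1],
                                                TEMPLATE_RANGES[[w]]$amp[2]), 1),
      center = vapply(wn, function(w) stats::runif(1, TEMPLATE_RANGES[[w]]$center[1],
                                                   TEMPLATE_RANGES[[w]]$center[2]), 1),
      width = vapply(wn, function(w) stats::runif(1, TEMPLATE_RANGES[[w]]$width[1],
                                                  TEMPLATE_RANGES[[w]]$width[2]), 1),
      stringsAsFactors = FALSE
    )
    new_subject_template(
      waves,
      hr_bpm = stats::runif(1, TEMPLATE_RANGES$hr_bpm[1], TEMPLATE_RANGES$hr_bpm[2]),
      hrv_s = stats::runif(1, TEMPLATE_RANGES$hrv_s[1], TEMPLATE_RANGES$hrv_s[2]),
      noise_mv = stats::runif(1, noise_range[1], noise_range[2]),
      wander_mv = stats::runif(1, TEMPLATE_RANGES$wander_mv[1],
                               TEMPLATE_RANGES$wander_mv[2]),
      wander_hz = stats::runif(1, TEMPLATE_RANGES$wander_hz[1],
                               TEMPLATE_RANGES$wander_hz[2])
    )
  })
}

#' @export
print.subject_template <- function(x, ...) {
  cat(sprintf("<subject_template> %g bpm (jitter %g s), noise %g mV\n",
              round(x$hr_bpm, 1), round(x$hrv_s, 3), round(x$noise_mv, 3)))
  print(x$waves, row.names = FALSE)
  invisible(x)
}

#' Generate a synthetic ECG record
#'
#' Concatenates beats whose onsets are spaced by the template's mean beat
#' period plus Gaussian jitter (`hrv_s`); each beat adds five Gaussian
#' bumps at the template's fractional centers and widths.  A sinusoidal
#' respiratory baseline wander (`wander_mv` at `wander_hz`, random phase)
#' and white noise of `noise_mv` are added, and the millivolt trace is
#' quantized to integer ADC units (gain 200/mV, offset 1024).
#' Deterministic given `(template, seed)`; with zero jitter, zero wander
#' and zero noise the output is periodic with period `60/hr_bpm` seconds.
#'
#' @param template a `subject_template`.
#' @param duration_s record duration in seconds.
#' @param fs sampling rate in Hz.
#' @param seed integer seed.
#' @param subject_id,record_id,timestamp labels attached to the result.
#' @return an [ecg_signal] of `round(duration_s * fs)` samples in ADC
#'   units.
#' @export
generate <- function(template, duration_s, fs, seed = 1L,
                     subject_id = NULL, record_id = NULL, timestamp = NULL) {
  stopifnot(inherits(template, "subject_template"),
            duration_s > 0, fs > 0)
  n <- round(duration_s * fs)
  tt <- (seq_len(n) - 1) / fs
  period <- 60 / template$hr_bpm
  x <- numeric(n)
  withr::with_seed(as.integer(seed), {
    n_beats <- ceiling(duration_s / period) + 3L
    jitter <- if (template$hrv_s > 0) {
      stats::rnorm(n_beats, 0, template$hrv_s)
    } else {
      numeric(n_beats)
    }
    intervals <- pmax(period + jitter, 0.3 * period)
    onsets <- cumsum(c(0, intervals))
    onsets <- onsets[onsets < duration_s + period]
    for (t0 in onsets) {
      for (w in seq_len(nrow(template$waves))) {
        amp <- template$waves$amp[w]
        ctr <- t0 + template$waves$center[w] * period
        sd_ <- template$waves$width[w] * period
        lo <- max(1L, floor((ctr - 5 * sd_) * fs) + 1L)
        hi <- min(n, ceiling((ctr + 5 * sd_) * fs) + 1L)
        if (lo <= hi) {
          idx <- lo:hi
          x[idx] <- x[idx] + amp * exp(-((tt[idx] - ctr)^2) / (2 * sd_^2))
        }
      }
    }
    if (template$wander_mv > 0) {
      phase <- stats::runif(1, 0, 2 * pi)
      x <- x + template$wander_mv *
        sin(2 * pi * template$wander_hz * tt + phase)
    }
    if (template$noise_mv > 0) {
      x <- x + stats::rnorm(n, 0, template$noise_mv)
    }
  })
  ecg_signal(round(x * ADC_GAIN) + ADC_ZERO, fs, subject_id = subject_id,
             record_id = record_id, timestamp = timestamp)
}

# Scale a template's morphology by a cumulative drift factor: wave
# amplitudes and widths and the heart rate move multiplicatively; centers,
# jitter, wander and noise stay put.
drift_template <- function(template, factor) {
  waves <- template$waves
  waves$amp <- waves$amp * factor
  waves$width <- pmin(waves$width * factor, 0.12)
  hr <- min(max(template$hr_bpm * factor, 35), 200)
  new_subject_template(waves, hr, template$hrv_s, template$noise_mv,
                       template$wander_mv, template$wander_hz,
                       template$drift_rate)
}

#' Generate a multi-session record history with optional drift
#'
#' Emulates a long-term enrolment database: `n_sessions` recording days,
#' `records_per_session` records each (default 20 s at 500 Hz).  Before
#' session k the template's wave amplitudes, widths and heart rate are
#' scaled by `(1 + drift_rate)^(k - 1)`, so a positive `drift_rate`
#' produces monotone morphological drift across sessions.  Records carry
#' strictly increasing `POSIXct` timestamps (sessions 21 days apart,
#' records one minute apart within a session) and per-record sub-seeds
#' derived from `seed`.
#'
#' @param template a `subject_template`.
#' @param n_sessions number of recording days, `>= 1`.
#' @param records_per_session records per day; either a scalar or a vector
#'   of length `n_sessions` (real long-term databases have uneven session
#'   sizes).
#' @param drift_rate per-session fractional parameter change (0 = none).
#' @param seed integer seed.
#' @param fs sampling rate in Hz (default 500).
#' @param record_seconds record duration (default 20).
#' @param start_date first session date.
#' @param session_gap_days days between sessions.
#' @return list of dated [ecg_signal] records in chronological order.
#' @export
generate_sessions <- function(template, n_sessions, records_per_session = 2L,
                              drift_rate = 0, seed = 1L, fs = 500,
                              record_seconds = 20,
                              start_date = as.Date("2005-01-04"),
                              session_gap_days = 21L) {
  stopifnot(n_sessions >= 1L, all(records_per_session >= 1L))
  rps <- rep_len(as.integer(records_per_session), n_sessions)
  out <- vector("list", sum(rps))
  i <- 0L
  for (k in seq_len(n_sessions)) {
    tk <- drift_template(template, (1 + drift_rate)^(k - 1L))
    day <- as.POSIXct(start_date, tz = "UTC") +
      (k - 1L) * session_gap_days * 86400
    for (r in seq_len(rps[k])) {
      i <- i + 1L
      out[[i]] <- generate(
        tk, record_seconds, fs, seed = derive_seed(seed, k, r),
        record_id = sprintf("s%02d_r%02d", k, r),
        timestamp = day + (r - 1L) * 60
      )
    }
  }
  out
}
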