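# Evolving per-subject model: the stored template's relative frequencies
# are blended with each newly enrolled record,
#   p(j) <- (1 - gamma) * p(j) + gamma * p_new(j),
# and ranks are recomputed from the blended frequencies.  This tracks the
# slow non-stationary drift of a subject's ECG statistics over days/months.

#' Profile a record as the mean of its two halves
#'
#' A record (nominally twice the segment duration, e.g. 20 s) is cut into
#' two equal halves, each half is profiled, the two relative-frequency
#' vectors are averaged element-wise and renormalized, and ranks are
#' recomputed from the averaged frequencies with the standard tie rule
#' (smaller word value wins).  Averaging frequencies rather than the
#' integer ranks keeps the result a valid probability vector, which is what
#' the evolving blend operates on.
#'
#' The returned profile's `counts`/`total_words` are `NA`: frequencies are
#' the authoritative state of averaged or blended profiles.
#'
#' @param record an [ecg_signal] of duration at least
#'   `2 * segment_seconds`.
#' @param params an [rbp_params].
#' @param segment_seconds half-record duration in seconds (default 10).
#' @return a `rank_profile` with averaged frequencies.
#' @export
record_profile <- function(record, params = rbp_params(),
                           segment_seconds = 10) {
  stopifnot(inherits(record, "ecg_signal"))
  n <- length(record$samples)
  need <- 2L * round(segment_seconds * record$fs)
  if (n < need) {
    abort("record too short: need >= %d samples (2 x %gs at %g Hz), got %d",
          need, segment_seconds, record$fs, n)
  }
  half <- floor(n / 2)
  p1 <- profile_signal(ecg_signal(record$samples[seq_len(half)], record$fs),
                       params)
  p2 <- profile_signal(ecg_signal(record$samples[half + seq_len(half)],
                                  record$fs), params)
  f <- (p1$freqs + p2$freqs) / 2
  f <- f / sum(f)
  new_rank_profile(rep(NA_integer_, length(f)), f, rank_from_counts(f),
                   NA_integer_, params$m)
}

#' Construct an evolving per-subject model
#'
#' @param profile a `rank_profile` (typically from [record_profile]) that
#'   seeds the model.
#' @param gamma blend weight in `[0, 1]` given to each new record.
#' @param params the [rbp_params] the model was built with.
#' @param subject_id opaque label.
#' @return an object of class `evolving_model` with fields `subject_id`,
#'   `profile`, `gamma`, `params` and `update_log` (data frame of absorbed
#'   records).
#' @export
evolving_model <- function(profile, gamma = 0.5, params = rbp_params(),
                           subject_id = NULL) {
  stopifnot(inherits(profile, "rank_profile"))
  if (gamma < 0 || gamma > 1) abort("evolving_model: gamma must lie in [0, 1]")
  structure(
    list(subject_id = subject_id, profile = profile, gamma = as.numeric(gamma),
         params = params,
         update_log = data.frame(timestamp = character(0),
                                 record_id = character(0),
                                 stringsAsFactors = FALSE)),
    class = "evolving_model"
  )
}

#' Blend a new record profile into an evolving model
#'
#' Applies `p <- (1 - gamma) * p + gamma * p_new` element-wise to the model
#' frequencies, recomputes ranks from the blended frequencies, and appends
#' the record to the update log.  `gamma = 0` leaves the model unchanged;
#' `gamma = 1` replaces it with the new profile.
#'
#' @param model an [evolving_model].
#' @param new_profile a `rank_profile` with the same `m` as the model.
#' @param timestamp,record_id optional provenance for the update log.
#' @return the updated `evolving_model`.
#' @export
update_model <- function(model, new_profile, timestamp = NA,
                         record_id = NA_character_) {
  stopifnot(inherits(model, "evolving_model"),
            inherits(new_profile, "rank_profile"))
  if (model$profile$m != new_profile$m) {
    abort("profile mismatch: model m=%d, new profile m=%d",
          model$profile$m, new_profile$m)
  }
  g <- model$gamma
  # the limits are exact: no renormalization noise at gamma = 0 or 1
  f <- if (g == 0) {
    model$profile$freqs
  } else if (g == 1) {
    new_profile$freqs
  } else {
    f <- (1 - g) * model$profile$freqs + g * new_profile$freqs
    f / sum(f)
  }
  model$profile <- new_rank_profile(rep(NA_integer_, length(f)), f,
                                    rank_from_counts(f), NA_integer_,
                                    model$profile$m)
  model$update_log <- rbind(
    model$update_log,
    data.frame(timestamp = as.character(timestamp),
               record_id = as.character(record_id),
               stringsAsFactors = FALSE)
  )
  model
}

#' @export
print.evolving_model <- function(x, ...) {
  cat(sprintf("<evolving_model> m=%d gamma=%g, %d update(s)%s\n",
              x$profile$m, x$gamma, nrow(x$update_log),
              if (is.null(x$subject_id)) "" else paste0(" [", x$subject_id, "]")))
  invisible(x)
}

#' Serialize an evolving model to JSON (the card payload)
#'
#' @param model an [evolving_model].
#' @param path output file; when `NULL` the JSON string is returned.
#' @return `path` invisibly, or the JSON string when `path` is `NULL`.
#' @export
model_to_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "evolving_model"))
  obj <- list(subject_id = model$subject_id, m = model$params$m,
              alpha = model$params$alpha, beta = model$params$beta,
              gamma = model$gamma, freqs = model$profile$freqs,
              ranks = model$profile$ranks,
              update_log = model$update_log)
  if (is.null(path)) {
    return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null"))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Run the long-term enrolment/verification protocol
#'
#' Records are ordered chronologically and grouped by calendar day.  The
#' model is seeded from the first valid record of the first day.  Every
#' later record is compared to the current model with [segment_distance]
#' (via its [record_profile]); on each day after the first, the day's first
#' valid record is absorbed into the model immediately after its own
#' comparison, so later records of the day meet the refreshed model.  A
#' record is valid when it is long enough for [record_profile].
#'
#' Alongside the evolving distances the same comparisons are made against
#' the frozen initial model (the non-evolving baseline).  The report sums
#' both distance series over the non-absorbed records of the days after
#' the first (`s_evolving`, `s_static`) and gives the improvement rate
#' `(s_static - s_evolving) / s_static` (`NA` when there are no such
#' records).
#'
#' @param records list of [ecg_signal] objects carrying `timestamp`s.
#' @param gamma blend weight (default 0.5: equal weight to model and new
#'   record).
#' @param params an [rbp_params].
#' @param segment_seconds half-record duration (default 10 s, i.e. 20 s
#'   records).
#' @return an object of class `longterm_report`: list with `table` (one
#'   row per record: date, record_id, distance_evolving, distance_static,
#'   absorbed, valid), `s_evolving`, `s_static`, `improvement_rate`,
#'   `gamma`, `params`, and the final `model`.
#' @export
run_longterm_protocol <- function(records, gamma = 0.5,
                                  params = rbp_params(),
                                  segment_seconds = 10) {
  if (!is.list(records) || length(records) == 0L) {
    abort("empty history: no records supplied")
  }
  ts <- lapply(records, function(r) r$timestamp)
  if (any(vapply(ts, is.null, logical(1)))) {
    abort("run_longterm_protocol: every record needs a timestamp")
  }
  tnum <- as.numeric(do.call(c, lapply(ts, as.POSIXct)))
  ord <- order(tnum)
  records <- records[ord]
  days <- as.Date(do.call(c, lapply(records, function(r) as.POSIXct(r$timestamp))))
  valid <- vapply(records, function(r) {
    length(r$samples) >= 2L * round(segment_seconds * r$fs)
  }, logical(1))
  if (!any(valid)) abort("run_longterm_protocol: no valid records")
  first_day <- min(days[valid])
  init_idx <- which(valid & days == first_day)[1L]

  init_profile <- record_profile(records[[init_idx]], params, segment_seconds)
  model <- evolving_model(init_profile, gamma = gamma, params = params,
                          subject_id = records[[init_idx]]$subject_id)
  static_profile <- init_profile

  n <- length(records)
  d_ev <- d_st <- rep(NA_real_, n)
  absorbed <- logical(n)
  absorbed[init_idx] <- TRUE
  absorbed_today <- ""

  for (i in seq_len(n)) {
    if (i == init_idx || !valid[i]) next
    rp <- record_profile(records[[i]], params, segment_seconds)
    d_ev[i] <- segment_distance(model$profile, rp)
    d_st[i] <- segment_distance(static_profile, rp)
    day_i <- as.character(days[i])
    if (days[i] > first_day && !identical(absorbed_today, day_i)) {
      model <- update_model(model, rp, timestamp = records[[i]]$timestamp,
                            record_id = records[[i]]$record_id %||% i)
      absorbed[i] <- TRUE
      absorbed_today <- day_i
    }
  }

  tab <- data.frame(
    date = days,
    record_id = vapply(seq_len(n), function(i) {
      as.character(records[[i]]$record_id %||% i)
    }, character(1)),
    distance_evolving = d_ev,
    distance_static = d_st,
    absorbed = absorbed,
    valid = valid,
    stringsAsFactors = FALSE
  )
  keep <- valid & !absorbed & days > first_day
  s_ev <- sum(d_ev[keep])
  s_st <- sum(d_st[keep])
  improvement <- if (!any(keep) || s_st == 0) NA_real_ else (s_st - s_ev) / s_st

  structure(list(table = tab, s_evolving = s_ev, s_static = s_st,
                 improvement_rate = improvement, gamma = gamma,
                 params = params, model = model),
            class = "longterm_report")
}

#' @export
print.longterm_report <- function(x, ...) {
  cat(sprintf("<longterm_report> %d records over %d day(s), gamma=%g\n",
              nrow(x$table), length(unique(x$table$date)), x$gamma))
  cat(sprintf("  sum of post-update distances: evolving %.4f, static %.4f\n",
              x$s_evolving, x$s_static))
  if (is.na(x$improvement_rate)) {
    cat("  improvement rate: not applicable (no post-update records)\n")
  } else {
    cat(sprintf("  improvement rate: %.2f%%\n", 100 * x$improvement_rate))
  }
  invisible(x)
}
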