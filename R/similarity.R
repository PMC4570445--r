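# Rank-distance similarity between segments (weighted rank distance) and
# between groups of segments (mean over the cartesian product).

#' Construct a segment set
#'
#' An ordered collection of equal-duration signal slices from one subject
#' or record, the basic unit for group comparison.
#'
#' @param segments list of numeric vectors (one per segment), all sampled
#'   at `fs`.
#' @param fs sampling rate in Hz.
#' @param subject_id opaque label.
#' @param segment_seconds nominal duration of each segment in seconds.
#' @return an object of class `segment_set`.
#' @export
segment_set <- function(segments, fs, subject_id = NULL,
                        segment_seconds = 10) {
  if (!is.list(segments) || length(segments) == 0L) {
    abort("segment_set: segments must be a non-empty list")
  }
  want <- round(segment_seconds * fs)
  segments <- lapply(segments, function(s) {
    s <- as.numeric(if (inherits(s, "ecg_signal")) s$samples else s)
    if (length(s) < want) {
      abort("segment_set: segment has %d samples, need >= %d", length(s), want)
    }
    s[seq_len(want)]  # truncate to exact nominal length
  })
  structure(list(segments = segments, fs = as.numeric(fs),
                 subject_id = subject_id,
                 segment_seconds = as.numeric(segment_seconds)),
            class = "segment_set")
}

#' @export
print.segment_set <- function(x, ...) {
  cat(sprintf("<segment_set> %d x %gs segments @ %g Hz%s\n",
              length(x$segments), x$segment_seconds, x$fs,
              if (is.null(x$subject_id)) "" else paste0(" [", x$subject_id, "]")))
  invisible(x)
}

#' Weighted rank distance between two profiles
#'
#' For profiles with frequencies p1, p2 and ranks R1, R2 over the `2^m`
#' word values, returns
#' `sum_j |R1(j) - R2(j)| p1(j) p2(j) / ((2^m - 1) * sum_j p1(j) p2(j))`.
#' The rank differences are weighted by the product of frequencies, so only
#' word values present in both profiles contribute; the `2^m - 1` factor
#' bounds the distance in `[0, 1]`.  Identical profiles give exactly 0 and
#' the measure is symmetric.
#'
#' When the two supports are disjoint the denominator vanishes; the
#' distance is then defined as 1 (maximal dissimilarity) with a warning.
#'
#' @param p1,p2 `rank_profile` objects (or evolving-model profiles) with
#'   equal `m`.
#' @return a single number in `[0, 1]`.
#' @export
segment_distance <- function(p1, p2) {
  if (p1$m != p2$m) {
    abort("profile mismatch: m differs (%d vs %d)", p1$m, p2$m)
  }
  if (sum(p1$freqs) <= 0 || sum(p2$freqs) <= 0) {
    abort("segment_distance: profiles must have positive total frequency")
  }
  w <- p1$freqs * p2$freqs
  den <- sum(w)
  if (den == 0) {
    warning("disjoint word supports: distance defined as 1", call. = FALSE)
    return(1)
  }
  sum(abs(p1$ranks - p2$ranks) * w) / ((2^p1$m - 1) * den)
}

# Profile every segment of a set once; reused across pairwise comparisons.
profile_set <- function(set, params) {
  lapply(set$segments,
         function(s) profile_signal(ecg_signal(s, set$fs), params))
}

# Mean segment distance over the full cartesian product of two profile
# lists (includes identical-segment zero pairs when the lists coincide).
group_distance_profiles <- function(pa, pb) {
  acc <- 0
  for (p1 in pa) for (p2 in pb) acc <- acc + segment_distance(p1, p2)
  acc / (length(pa) * length(pb))
}

#' Average group distance between two segment sets
#'
#' The arithmetic mean of [segment_distance] over all pairs of one segment
#' from each set.  With `A` and `B` the same set this is the intra-group
#' distance (the mean includes the zero diagonal pairs); otherwise the
#' inter-group distance.
#'
#' @param A,B `segment_set` objects.
#' @param params an [rbp_params].
#' @return a single number in `[0, 1]`.
#' @export
group_distance <- function(A, B, params = rbp_params()) {
  stopifnot(inherits(A, "segment_set"), inherits(B, "segment_set"))
  if (length(A$segments) == 0L || length(B$segments) == 0L) {
    abort("empty group: both segment sets must be non-empty")
  }
  pa <- profile_set(A, params)
  pb <- if (identical(A, B)) pa else profile_set(B, params)
  group_distance_profiles(pa, pb)
}

#' Pairwise group-distance matrix over several segment sets
#'
#' Materializes the symmetric matrix of [group_distance] over all pairs of
#' sets; diagonal entries are intra-group distances.
#'
#' @param sets non-empty list of `segment_set` objects.
#' @param params an [rbp_params].
#' @return a symmetric numeric matrix with subject labels as dimnames.
#' @export
pairwise_matrix <- function(sets, params = rbp_params()) {
  if (!is.list(sets) || length(sets) == 0L) {
    abort("pairwise_matrix: need at least one segment set")
  }
  n <- length(sets)
  profs <- lapply(sets, profile_set, params = params)
  labels <- vapply(seq_len(n), function(i) {
    sets[[i]]$subject_id %||% sprintf("S%02d", i)
  }, character(1))
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n)) {
    for (j in i:n) {
      d <- group_distance_profiles(profs[[i]], profs[[j]])
      m[i, j] <- d
      m[j, i] <- d
    }
  }
  m
}

#' Write a labeled distance matrix to CSV
#'
#' @param mat numeric matrix with dimnames (e.g. from [pairwise_matrix]).
#' @param path output CSV path.
#' @param digits decimal places (at least 6).
#' @return `path` invisibly.
#' @export
write_distance_csv <- function(mat, path, digits = 8) {
  stopifnot(is.matrix(mat), digits >= 6)
  fm <- matrix(sprintf(paste0("%.", digits, "f"), mat), nrow(mat),
               dimnames = dimnames(mat))
  utils::write.csv(as.data.frame(fm), path, quote = FALSE)
  invisible(path)
}

#' Read a distance matrix written by [write_distance_csv]
#'
#' @param path CSV path.
#' @return numeric matrix with dimnames.
#' @export
read_distance_csv <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  as.matrix(df)
}
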