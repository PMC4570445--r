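# Core reduced-binary-pattern encoding: signal -> bits -> m-bit words ->
# count/frequency/rank profile.

#' Reduce an ECG signal to a binary sequence
#'
#' Emits bit t = 1 iff
#' `samples[alpha*t + 1] > beta + samples[alpha*(t-1) + 1]` (1-based),
#' else 0, for t = 1, 2, ... while `alpha*t + 1 <= N`: consecutive samples
#' of the `alpha`-strided grid `x[1], x[alpha+1], x[2*alpha+1], ...` are
#' compared, so `alpha` acts as an effective down-sampler (at `alpha = 2`
#' this is exactly the comparison of `x[2t+1]` against `x[2t-1]`).  With
#' `alpha = 1, beta = 0` it is the plain comparison of consecutive
#' samples: bit i is 1 iff the signal rises from sample i to sample i+1.
#' `beta` requires a rise to exceed an amplitude threshold before a 1 is
#' emitted.  Equality never emits a 1.
#'
#' The encoding is invariant to adding a constant offset to the signal and,
#' when `beta = 0`, to multiplying it by a positive constant.
#'
#' @param signal an [ecg_signal].
#' @param params an [rbp_params]; only `alpha` and `beta` are used.
#' @return an object of class `binary_sequence`: list with `bits` (integer
#'   vector of 0/1), `source_length` (N of the input) and `alpha_used`.
#' @examples
#' reduce_binary(ecg_signal(c(1, 2, 3, 4, 5), fs = 1), rbp_params(m = 2))$bits
#' @export
reduce_binary <- function(signal, params = rbp_params()) {
  stopifnot(inherits(signal, "ecg_signal"), inherits(params, "rbp_params"))
  x <- signal$samples
  n <- length(x)
  alpha <- params$alpha
  t_max <- floor((n - 1) / alpha)
  if (t_max < 1L) {
    abort("signal too short: need at least %d samples for one comparison at alpha=%d, got %d",
          alpha + 1L, alpha, n)
  }
  t <- seq_len(t_max)
  bits <- as.integer(x[alpha * t + 1L] > params$beta + x[alpha * (t - 1L) + 1L])
  structure(list(bits = bits, source_length = n, alpha_used = alpha),
            class = "binary_sequence")
}

#' Group a binary sequence into m-bit words
#'
#' Slides a window of width `m` with stride 1 over the bits; each window is
#' read as an unsigned integer with the earliest bit most significant, so
#' bits `0,0,0,1` give word 1 and `0,1,1,1` give word 7.
#'
#' @param bits a `binary_sequence` (from [reduce_binary]) or a plain 0/1
#'   vector.
#' @param m word length in bits.
#' @return an object of class `word_sequence`: list with integer `words`
#'   (each in `[0, 2^m - 1]`, length `length(bits) - m + 1`) and `m`.
#' @examples
#' words_from_bits(c(0, 0, 0, 1), m = 4)$words  # 1
#' @export
words_from_bits <- function(bits, m) {
  if (inherits(bits, "binary_sequence")) bits <- bits$bits
  bits <- as.integer(bits)
  if (anyNA(bits) || any(bits != 0L & bits != 1L)) {
    abort("words_from_bits: bits must all be 0 or 1")
  }
  m <- as.integer(m)
  nb <- length(bits)
  if (nb < m) {
    abort("insufficient bits: need at least m=%d bits, got %d", m, nb)
  }
  # embed() row k is bits[k+m-1], ..., bits[k] (reversed in time), so the
  # weight of column j is 2^(j-1) to make the earliest bit most significant.
  if (m == 1L) {
    words <- bits
  } else {
    words <- as.integer(stats::embed(bits, m) %*% 2^(0:(m - 1L)))
  }
  structure(list(words = words, m = m), class = "word_sequence")
}

# Ranks from a count (or frequency) vector: rank 1 = largest value; ties
# broken toward the smaller word value so ranks are always a permutation.
rank_from_counts <- function(counts) {
  ord <- order(-counts, seq_along(counts))
  r <- integer(length(counts))
  r[ord] <- seq_along(counts)
  r
}

new_rank_profile <- function(counts, freqs, ranks, total_words, m) {
  structure(list(counts = counts, freqs = freqs, ranks = ranks,
                 total_words = total_words, m = m),
            class = "rank_profile")
}

#' Count m-bit words and rank them by frequency
#'
#' Tallies occurrences of every word value `j` in `[0, 2^m - 1]`, converts
#' them to relative frequencies, and assigns descending-frequency ranks
#' (rank 1 = most frequent).  Ties in count are broken toward the smaller
#' word value, so the ranks are always a full permutation of `1:2^m`;
#' zero-count words occupy the worst ranks under the same rule.
#'
#' @param words a `word_sequence` (from [words_from_bits]) or an integer
#'   vector of word values, in which case `m` must be supplied.
#' @param m word length; ignored when `words` is a `word_sequence`.
#' @return an object of class `rank_profile`: list with `counts`, `freqs`,
#'   `ranks` (each length `2^m`), `total_words` and `m`.  `freqs[j+1]` is
#'   the relative frequency of word value `j`.
#' @examples
#' p <- count_and_rank(c(1L, 1L, 7L, 0L), m = 4)
#' p$freqs[2]          # word value 1 appears half the time
#' which(p$ranks == 1) # most frequent word value + 1
#' @export
count_and_rank <- function(words, m = NULL) {
  if (inherits(words, "word_sequence")) {
    m <- words$m
    w <- words$words
  } else {
    if (is.null(m)) abort("count_and_rank: m is required for a bare vector")
    w <- as.integer(words)
  }
  m <- as.integer(m)
  if (length(w) < 1L) abort("empty profile: no words to count")
  k <- 2L^m
  if (any(w < 0L | w >= k)) {
    abort("count_and_rank: word values must lie in [0, %d]", k - 1L)
  }
  counts <- tabulate(w + 1L, nbins = k)
  total <- length(w)
  new_rank_profile(counts, counts / total, rank_from_counts(counts),
                   total, m)
}

#' Profile a signal in one call
#'
#' Composition of [reduce_binary], [words_from_bits] and [count_and_rank]:
#' the full encoding from raw samples to a count/frequency/rank profile.
#'
#' @inheritParams reduce_binary
#' @return a `rank_profile` (see [count_and_rank]).
#' @examples
#' sig <- ecg_signal(cumsum(rnorm(500)), fs = 100)
#' profile_signal(sig, rbp_params(m = 4))
#' @export
profile_signal <- function(signal, params = rbp_params()) {
  count_and_rank(words_from_bits(reduce_binary(signal, params), params$m))
}

#' @export
print.rank_profile <- function(x, ...) {
  cat(sprintf("<rank_profile> m=%d, %s words, %d/%d word values seen\n",
              x$m,
              if (is.na(x$total_words)) "blended" else x$total_words,
              sum(x$freqs > 0), length(x$freqs)))
  top <- order(x$ranks)[seq_len(min(5L, length(x$ranks)))]
  cat("  top words (value:freq):",
      paste(sprintf("%d:%.3f", top - 1L, x$freqs[top]), collapse = " "), "\n")
  invisible(x)
}

#' Serialize a rank profile to JSON
#'
#' @param profile a `rank_profile`.
#' @param path output file; when `NULL` the JSON string is returned.
#' @return `path` invisibly, or the JSON string when `path` is `NULL`.
#' @export
profile_to_json <- function(profile, path = NULL) {
  stopifnot(inherits(profile, "rank_profile"))
  obj <- list(m = profile$m, total_words = profile$total_words,
              counts = profile$counts, freqs = profile$freqs,
              ranks = profile$ranks)
  if (is.null(path)) {
    return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null"))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read a rank profile from JSON written by [profile_to_json]
#'
#' @param path JSON file path.
#' @return a `rank_profile`.
#' @export
profile_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_rank_profile(
    counts = if (is.null(obj$counts)) rep(NA_integer_, 2^obj$m)
             else as.integer(obj$counts),
    freqs = as.numeric(obj$freqs),
    ranks = as.integer(obj$ranks),
    total_words = if (is.null(obj$total_words)) NA_integer_
                  else as.integer(obj$total_words),
    m = as.integer(obj$m)
  )
}
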