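# Independent brute-force oracles, written as literal loops so they share
# no code path with the implementation.

oracle_count <- function(words, m) {
  counts <- integer(2^m)
  for (w in words) counts[w + 1L] <- counts[w + 1L] + 1L
  counts
}

# Rank by descending frequency; ties broken toward the smaller word value.
oracle_ranks <- function(freqs) {
  k <- length(freqs)
  r <- integer(k)
  for (j in seq_len(k)) {
    r[j] <- 1L
    for (l in seq_len(k)) {
      if (freqs[l] > freqs[j] || (freqs[l] == freqs[j] && l < j)) {
        r[j] <- r[j] + 1L
      }
    }
  }
  r
}

oracle_segment_distance <- function(p1, p2) {
  k <- 2^p1$m
  num <- 0
  den <- 0
  for (j in seq_len(k)) {
    num <- num + abs(p1$ranks[j] - p2$ranks[j]) * p1$freqs[j] * p2$freqs[j]
    den <- den + p1$freqs[j] * p2$freqs[j]
  }
  num / ((2^p1$m - 1) * den)
}

oracle_group_distance <- function(profs_a, profs_b) {
  total <- 0
  for (pa in profs_a) {
    for (pb in profs_b) {
      total <- total + oracle_segment_distance(pa, pb)
    }
  }
  total / (length(profs_a) * length(profs_b))
}

oracle_success_errors <- function(mat) {
  n <- nrow(mat)
  errors <- 0L
  for (l in seq_len(n)) {
    for (k in seq_len(n)) {
      if (l != k && mat[l, k] <= mat[l, l]) errors <- errors + 1L
    }
  }
  errors
}

# A synthetic rank profile with continuous (tie-free) random frequencies.
random_profile <- function(m, seed) {
  withr::with_seed(seed, {
    f <- stats::rexp(2^m)
    f <- f / sum(f)
    rbpecg:::new_rank_profile(rep(NA_integer_, 2^m), f, oracle_ranks(f),
                              NA_integer_, as.integer(m))
  })
}
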