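test_that("reduce_binary matches the hand-evaluated comparison rule", {
  p <- function(alpha = 1, beta = 0) rbp_params(m = 2, alpha = alpha, beta = beta)
  expect_equal(reduce_binary(ecg_signal(1:5, 1), p())$bits, c(1L, 1L, 1L, 1L))
  expect_equal(reduce_binary(ecg_signal(5:1, 1), p())$bits, c(0L, 0L, 0L, 0L))
  # strided: compare x3 vs x1, x5 vs x3, x7 vs x5
  expect_equal(
    reduce_binary(ecg_signal(c(0, 2, 1, 3, 2, 4, 3), 1), p(alpha = 2))$bits,
    c(1L, 1L, 1L))
  # rises of 0.5 do not exceed beta = 1; equality maps to 0
  expect_equal(
    reduce_binary(ecg_signal(c(0, 0.5, 1), 1), p(beta = 1))$bits, c(0L, 0L))
  expect_equal(reduce_binary(ecg_signal(c(2, 2, 2), 1), p())$bits, c(0L, 0L))
})

test_that("reduce_binary reports the minimum length in its error", {
  expect_error(reduce_binary(ecg_signal(c(1, 2), 1), rbp_params(alpha = 5)),
               "signal too short.*6 samples")
})

test_that("binary sequence length and invariance properties hold", {
  withr::with_seed(11, {
    for (rep in 1:25) {
      n <- sample(10:300, 1)
      alpha <- sample(1:3, 1)
      x <- cumsum(rnorm(n))
      sig <- ecg_signal(x, 250)
      b <- reduce_binary(sig, rbp_params(m = 4, alpha = alpha))
      expect_equal(length(b$bits), floor((n - 1) / alpha))
      if (alpha == 1) {
        # alpha = 1, beta = 0 is the plain consecutive comparison
        expect_equal(b$bits, as.integer(diff(x) > 0))
      }
      # offset invariance (any beta), positive-scale invariance (beta = 0)
      beta <- sample(c(0, 1), 1)
      pb <- rbp_params(m = 4, alpha = alpha, beta = beta)
      expect_identical(reduce_binary(ecg_signal(x + 57.3, 250), pb)$bits,
                       reduce_binary(sig, pb)$bits)
      p0 <- rbp_params(m = 4, alpha = alpha, beta = 0)
      expect_identical(reduce_binary(ecg_signal(x * 3.7, 250), p0)$bits,
                       reduce_binary(sig, p0)$bits)
    }
  })
})

test_that("words_from_bits reads the earliest bit as most significant", {
  expect_equal(words_from_bits(c(0, 0, 0, 1), m = 4)$words, 1L)
  expect_equal(words_from_bits(c(0, 1, 1, 1), m = 4)$words, 7L)
  expect_equal(words_from_bits(c(1, 0, 1, 0, 1), m = 2)$words,
               c(2L, 1L, 2L, 1L))
  expect_equal(words_from_bits(c(0, 0, 0, 0), m = 4)$words, 0L)
  expect_error(words_from_bits(c(0, 1), m = 4), "insufficient bits")
})

test_that("word count arithmetic holds on random inputs", {
  withr::with_seed(12, {
    for (rep in 1:20) {
      nb <- sample(5:200, 1)
      m <- sample(2:8, 1)
      if (nb < m) next
      bits <- sample(0:1, nb, replace = TRUE)
      ws <- words_from_bits(bits, m)
      expect_equal(length(ws$words), nb - m + 1)
      expect_true(all(ws$words >= 0 & ws$words <= 2^m - 1))
    }
  })
})

test_that("count_and_rank counts, normalizes and applies the tie rule", {
  p <- count_and_rank(c(1L, 1L, 7L, 0L), m = 4)
  expect_equal(p$counts[c(1, 2, 8)], c(1L, 2L, 1L))  # words 0, 1, 7
  expect_equal(p$total_words, 4L)
  expect_equal(p$freqs[2], 0.5)
  expect_equal(p$ranks[2], 1L)        # word 1 most frequent
  expect_equal(p$ranks[1], 2L)        # tie 0 vs 7 broken toward 0
  expect_equal(p$ranks[8], 3L)
  # degenerate single-value distribution
  q <- count_and_rank(rep(5L, 9), m = 3)
  expect_equal(q$ranks[6], 1L)
  expect_equal(q$freqs[6], 1)
  expect_error(count_and_rank(integer(0), m = 3), "empty profile")
})

test_that("profiles agree with the brute-force oracle on random signals", {
  withr::with_seed(13, {
    for (rep in 1:40) {
      n <- sample(20:500, 1)
      m <- sample(2:8, 1)
      alpha <- sample(1:3, 1)
      beta <- sample(c(0, 1), 1)
      sig <- ecg_signal(cumsum(rnorm(n)), 250)
      params <- rbp_params(m = m, alpha = alpha, beta = beta)
      bits <- reduce_binary(sig, params)
      if (length(bits$bits) < m) next
      ws <- words_from_bits(bits, m)
      prof <- count_and_rank(ws)
      expect_identical(prof$counts, oracle_count(ws$words, m))
      expect_identical(prof$ranks, oracle_ranks(prof$counts))
      # conservation
      expect_equal(sum(prof$counts), prof$total_words)
      expect_lt(abs(sum(prof$freqs) - 1), 1e-9)
      # ranks form a permutation ordered consistently with counts
      expect_setequal(prof$ranks, seq_len(2^m))
      # one-call composition is identical
      expect_identical(profile_signal(sig, params), prof)
    }
  })
})

test_that("profile length arithmetic matches the stated formula", {
  withr::with_seed(14, {
    sig <- ecg_signal(rnorm(4000), 360)
    prof <- profile_signal(sig, rbp_params(m = 8))
    expect_equal(prof$total_words, (4000 - 1) - 8 + 1)
  })
})

test_that("rank profiles survive a JSON round trip", {
  withr::with_seed(15, {
    prof <- profile_signal(ecg_signal(cumsum(rnorm(300)), 100),
                           rbp_params(m = 5))
    path <- withr::local_tempfile(fileext = ".json")
    profile_to_json(prof, path)
    back <- profile_from_json(path)
    expect_equal(back$counts, prof$counts)
    expect_equal(back$freqs, prof$freqs)
    expect_equal(back$ranks, prof$ranks)
    expect_equal(back$m, prof$m)
  })
})

test_that("parameter validation rejects out-of-range knobs", {
  expect_error(rbp_params(m = 0), "m must be")
  expect_error(rbp_params(m = 17), "m must be")
  expect_error(rbp_params(alpha = 0), "alpha")
  expect_error(rbp_params(beta = -1), "beta")
  expect_error(rbp_params(gamma = 1.5), "gamma")
  expect_error(ecg_signal(1, 100), "at least 2 samples")
  expect_error(ecg_signal(1:10, 0), "fs")
})
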