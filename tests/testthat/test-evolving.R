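test_that("record_profile averages the two half-record profiles", {
  params <- rbp_params(m = 1)
  # halves: strictly falling then strictly rising, 5 samples each at 5 Hz
  rec <- ecg_signal(c(5, 4, 3, 2, 1, 1, 2, 3, 4, 5), fs = 5)
  rp <- record_profile(rec, params, segment_seconds = 1)
  expect_equal(rp$freqs, c(0.5, 0.5))
  expect_equal(rp$ranks, c(1L, 2L))  # tie broken toward the smaller word
  expect_true(is.na(rp$total_words))

  # identical halves reduce to either half's profile
  withr::with_seed(31, {
    half <- cumsum(rnorm(50))
    rec2 <- ecg_signal(c(half, half), fs = 5)
    rp2 <- record_profile(rec2, rbp_params(m = 3), segment_seconds = 10)
    ph <- profile_signal(ecg_signal(half, 5), rbp_params(m = 3))
    expect_equal(rp2$freqs, ph$freqs)
    expect_equal(rp2$ranks, ph$ranks)
  })
  expect_error(record_profile(ecg_signal(1:9, 5), params, 1), "record too short")
})

test_that("record_profile frequencies always lie on the simplex", {
  withr::with_seed(32, {
    for (rep in 1:10) {
      rec <- ecg_signal(cumsum(rnorm(200)), fs = 10)
      rp <- record_profile(rec, rbp_params(m = sample(2:6, 1)),
                           segment_seconds = 10)
      expect_lt(abs(sum(rp$freqs) - 1), 1e-9)
      expect_true(all(rp$freqs >= 0))
    }
  })
})

test_that("update_model has exact identity and replacement limits", {
  p0 <- random_profile(4, 41)
  pn <- random_profile(4, 42)
  m0 <- evolving_model(p0, gamma = 0, params = rbp_params(m = 4))
  expect_equal(update_model(m0, pn)$profile$freqs, p0$freqs)
  m1 <- evolving_model(p0, gamma = 1, params = rbp_params(m = 4))
  expect_equal(update_model(m1, pn)$profile$freqs, pn$freqs)
  expect_equal(update_model(m1, pn)$profile$ranks, pn$ranks)
})

test_that("update_model blends frequencies per the weighted rule", {
  p <- rbpecg:::new_rank_profile(NA, c(0.8, 0.2), c(1L, 2L), NA, 1L)
  pn <- rbpecg:::new_rank_profile(NA, c(0.4, 0.6), c(2L, 1L), NA, 1L)
  mod <- evolving_model(p, gamma = 0.5, params = rbp_params(m = 1))
  out <- update_model(mod, pn, timestamp = "2005-01-01", record_id = "r2")
  expect_equal(out$profile$freqs, c(0.6, 0.4))
  expect_equal(out$profile$ranks, c(1L, 2L))
  expect_equal(nrow(out$update_log), 1L)
  expect_equal(out$update_log$record_id, "r2")
  expect_error(update_model(mod, random_profile(4, 1)), "profile mismatch")
})

test_that("blended frequencies stay on the simplex under repeated updates", {
  withr::with_seed(43, {
    mod <- evolving_model(random_profile(5, 1), gamma = 0.3,
                          params = rbp_params(m = 5))
    for (i in 1:20) {
      mod <- update_model(mod, random_profile(5, 100 + i))
      expect_lt(abs(sum(mod$profile$freqs) - 1), 1e-9)
      expect_true(all(mod$profile$freqs >= 0))
      expect_setequal(mod$profile$ranks, 1:32)
    }
    expect_equal(nrow(mod$update_log), 20L)
  })
})

test_that("the long-term protocol orders, scores and absorbs correctly", {
  records <- make_history(seed = 1)
  rep <- run_longterm_protocol(records, gamma = 0.5,
                               params = rbp_params(m = 8, alpha = 13, beta = 1))
  tab <- rep$table
  # one absorbed record on the first day (the seed) and on each later day
  expect_equal(sum(tab$absorbed), 5L)
  expect_true(all(tapply(tab$absorbed, tab$date, sum) == 1))
  first_of_day <- !duplicated(tab$date)
  expect_true(all(tab$absorbed[first_of_day]))
  # sums cover exactly the non-absorbed records after day one
  keep <- !tab$absorbed & tab$date > tab$date[1]
  expect_equal(rep$s_evolving, sum(tab$distance_evolving[keep]))
  expect_equal(rep$s_static, sum(tab$distance_static[keep]))
  # shuffling the input order must not change the report
  rep2 <- run_longterm_protocol(records[c(10:16, 1:9, 17:20)], gamma = 0.5,
                                params = rbp_params(m = 8, alpha = 13, beta = 1))
  expect_equal(rep2$table$record_id, tab$record_id)
  expect_equal(rep2$s_evolving, rep$s_evolving)
})

test_that("gamma = 0 reduces the protocol to the static baseline", {
  records <- make_history(seed = 2, n_sessions = 3,
                          records_per_session = c(2, 3, 2))
  rep <- run_longterm_protocol(records, gamma = 0,
                               params = rbp_params(m = 8, alpha = 13, beta = 1))
  expect_equal(rep$s_evolving, rep$s_static)
  expect_equal(rep$improvement_rate, 0)
})

test_that("single-day histories yield a not-applicable improvement", {
  records <- make_history(seed = 3, n_sessions = 1, records_per_session = 3)
  rep <- run_longterm_protocol(records, gamma = 0.5,
                               params = rbp_params(m = 8, alpha = 13, beta = 1))
  expect_equal(rep$s_evolving, 0)
  expect_true(is.na(rep$improvement_rate))
  expect_error(run_longterm_protocol(list()), "empty history")
})

test_that("drifted histories benefit from the evolving update", {
  records <- make_history(seed = 1, drift_rate = 0.05)
  rep <- run_longterm_protocol(records, gamma = 0.5,
                               params = rbp_params(m = 8, alpha = 13, beta = 1))
  expect_gt(rep$improvement_rate, 0)
})

test_that("evolving models serialize to the card JSON payload", {
  mod <- evolving_model(random_profile(3, 5), gamma = 0.5,
                        params = rbp_params(m = 3, alpha = 2, beta = 1),
                        subject_id = "person_01")
  mod <- update_model(mod, random_profile(3, 6), timestamp = "2005-03-15",
                      record_id = "r10")
  path <- withr::local_tempfile(fileext = ".json")
  model_to_json(mod, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$subject_id, "person_01")
  expect_equal(back$m, 3)
  expect_equal(back$gamma, 0.5)
  expect_equal(back$freqs, mod$profile$freqs)
  expect_equal(back$update_log$record_id, "r10")
})
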