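# Cohort and record fixtures, generated in code at test time.

make_cohort <- function(seed, n_subjects, n_segments, fs = 360,
                        segment_seconds = 10, scenario = "ambulatory") {
  lapply(seq_len(n_subjects), function(i) {
    tpl <- sample_subject(derive_seed(seed, i), scenario = scenario)
    sig <- generate(tpl, duration_s = n_segments * segment_seconds, fs = fs,
                    seed = derive_seed(seed, i, 999L),
                    subject_id = sprintf("subj%02d", i))
    segment(sig, segment_seconds, max_segments = n_segments)
  })
}

make_history <- function(seed, n_sessions = 5,
                         records_per_session = c(2, 7, 4, 4, 3),
                         drift_rate = 0.05) {
  tpl <- sample_subject(derive_seed(seed, 7L), scenario = "resting")
  generate_sessions(tpl, n_sessions = n_sessions,
                    records_per_session = records_per_session,
                    drift_rate = drift_rate, seed = seed)
}

write_csv_fixture <- function(samples, path) {
  utils::write.table(data.frame(sample = samples), path, sep = ",",
                     row.names = FALSE, col.names = TRUE, quote = FALSE)
  path
}
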