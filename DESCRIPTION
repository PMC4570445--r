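Package: rbpecg
Title: Reduced Binary Pattern Algorithms for ECG-Based Identity Verification
Version: 0.1.0
Authors@R:
    person("rbpecg", "maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Symbolic-dynamics tooling for human identity verification from
    raw single-lead electrocardiogram (ECG) signals.  A signal is reduced to
    a binary sequence by the sign of (optionally interval-strided,
    amplitude-thresholded) sample differences, grouped into m-bit words, and
    summarised by word counts, relative frequencies and descending-frequency
    ranks.  Segments are compared with a weighted rank-distance, subjects
    with the average pairwise segment distance, and long-term non-stationary
    drift is handled by an evolving per-subject model that blends new
    relative frequencies into the stored template.  Includes verification
    metrics (success rate, false acceptance/rejection with threshold
    tuning), readers and writers for WFDB and plain CSV records, a seeded
    multi-subject synthetic ECG generator, and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
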