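# Record loading (WFDB header/signal pairs, one-column CSV/text) and
# segmentation into fixed-duration windows.

#' Load an ECG record from file
#'
#' Supported formats:
#' * `wfdb` — a PhysioNet-style header/signal pair; pass the record path
#'   with or without the `.hea` extension.  Sampling rate comes from the
#'   header; samples are returned as raw ADC integers (no gain/baseline
#'   correction, no filtering).
#' * `csv` — one-column (or multi-column) numeric text, optional header
#'   line; `fs` must be supplied, `channel` selects the column.
#'
#' `format = "auto"` picks by extension (`.hea` or a bare path with a
#' `.hea` file next to it means WFDB; `.csv`/`.txt` means CSV).
#'
#' @param path record path.
#' @param format one of `"auto"`, `"wfdb"`, `"csv"`.
#' @param fs sampling rate in Hz, required for CSV input.
#' @param channel 1-based channel/column index (default 1).
#' @param subject_id,record_id,timestamp optional labels attached to the
#'   returned signal.
#' @return an [ecg_signal].
#' @export
load_record <- function(path, format = c("auto", "wfdb", "csv"), fs = NULL,
                        channel = 1L, subject_id = NULL, record_id = NULL,
                        timestamp = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "hea" || file.exists(paste0(sub("\\.hea$", "", path), ".hea"))) {
      "wfdb"
    } else if (ext %in% c("csv", "txt", "tsv", "dat0", "")) {
      "csv"
    } else {
      "csv"
    }
  }
  if (format == "wfdb") {
    rec <- read_wfdb(path, channel = channel)
    return(ecg_signal(rec$samples, rec$fs, subject_id = subject_id,
                      record_id = record_id %||% rec$record_name,
                      timestamp = timestamp))
  }
  if (!file.exists(path)) abort("missing file: %s", path)
  if (is.null(fs)) abort("sampling rate fs is required for CSV input")
  first <- readLines(path, n = 1L)
  has_header <- is.na(suppressWarnings(
    as.numeric(strsplit(first, "[,\t ]+")[[1]][1])))
  df <- utils::read.csv(path, header = has_header)
  if (channel < 1L || channel > ncol(df)) {
    abort("channel %d out of range: file has %d column(s)", channel, ncol(df))
  }
  ecg_signal(as.numeric(df[[channel]]), fs, subject_id = subject_id,
             record_id = record_id %||% basename(path), timestamp = timestamp)
}

#' Write a signal to one-column CSV
#'
#' @param signal an [ecg_signal].
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_csv_record <- function(signal, path) {
  stopifnot(inherits(signal, "ecg_signal"))
  utils::write.table(data.frame(sample = signal$samples), path,
                     row.names = FALSE, col.names = TRUE, sep = ",",
                     quote = FALSE)
  invisible(path)
}

#' Cut a signal into fixed-duration segments
#'
#' Non-overlapping consecutive windows of `round(segment_seconds * fs)`
#' samples taken from the start of the signal; a trailing partial window
#' is dropped.  Sample values are passed through unmodified.
#'
#' @param signal an [ecg_signal].
#' @param segment_seconds window duration in seconds (default 10).
#' @param max_segments optional cap on the number of segments returned.
#' @return a [segment_set].
#' @export
segment <- function(signal, segment_seconds = 10, max_segments = NULL) {
  stopifnot(inherits(signal, "ecg_signal"))
  window <- round(segment_seconds * signal$fs)
  n <- length(signal$samples)
  nseg <- floor(n / window)
  if (nseg < 1L) {
    abort("signal shorter than one segment: %d samples < window of %d",
          n, window)
  }
  if (!is.null(max_segments)) nseg <- min(nseg, as.integer(max_segments))
  segs <- lapply(seq_len(nseg), function(k) {
    signal$samples[((k - 1L) * window + 1L):(k * window)]
  })
  segment_set(segs, fs = signal$fs, subject_id = signal$subject_id,
              segment_seconds = segment_seconds)
}
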