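# Minimal WFDB (PhysioNet) record support: header parsing plus signal
# formats 16 (16-bit little-endian) and 212 (packed 12-bit pairs, the
# MIT-BIH distribution format).  Samples are ADC integers; no gain or
# baseline correction is applied.

parse_wfdb_header <- function(hea_path) {
  if (!file.exists(hea_path)) abort("missing file: %s", hea_path)
  lines <- readLines(hea_path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  rec_tok <- strsplit(trimws(lines[1L]), "\\s+")[[1]]
  record_name <- sub("/.*$", "", rec_tok[1L])
  nsig <- as.integer(rec_tok[2L])
  fs <- if (length(rec_tok) >= 3L) as.numeric(sub("/.*$", "", rec_tok[3L])) else 250
  nsamp <- if (length(rec_tok) >= 4L) as.integer(rec_tok[4L]) else NA_integer_
  if (length(lines) < 1L + nsig) {
    abort("WFDB header %s: expected %d signal lines", hea_path, nsig)
  }
  sig <- lapply(seq_len(nsig), function(i) {
    tok <- strsplit(trimws(lines[1L + i]), "\\s+")[[1]]
    list(file = tok[1L],
         fmt = as.integer(sub("^([0-9]+).*$", "\\1", tok[2L])),
         gain = if (length(tok) >= 3L)
           as.numeric(sub("^([-0-9.]+).*$", "\\1", tok[3L])) else 200,
         description = if (length(tok) >= 9L)
           paste(tok[9:length(tok)], collapse = " ") else sprintf("sig%d", i))
  })
  list(record_name = record_name, nsig = nsig, fs = fs, nsamp = nsamp,
       signals = sig)
}

decode_fmt212 <- function(bytes, n_samples) {
  b <- as.integer(bytes)
  n_frames <- length(b) %/% 3L
  b1 <- b[3L * seq_len(n_frames) - 2L]
  b2 <- b[3L * seq_len(n_frames) - 1L]
  b3 <- b[3L * seq_len(n_frames)]
  s1 <- b1 + 256L * (b2 %% 16L)
  s2 <- b3 + 256L * (b2 %/% 16L)
  s1 <- ifelse(s1 > 2047L, s1 - 4096L, s1)
  s2 <- ifelse(s2 > 2047L, s2 - 4096L, s2)
  out <- numeric(2L * n_frames)
  out[c(TRUE, FALSE)] <- s1
  out[c(FALSE, TRUE)] <- s2
  out[seq_len(min(n_samples, length(out)))]
}

encode_fmt212 <- function(samples) {
  s <- as.integer(round(samples))
  if (any(s < -2048L | s > 2047L)) {
    abort("format 212 stores 12-bit samples: values must lie in [-2048, 2047]")
  }
  if (length(s) %% 2L == 1L) s <- c(s, 0L)  # pad to full 3-byte frames
  u <- s %% 4096L
  u1 <- u[c(TRUE, FALSE)]
  u2 <- u[c(FALSE, TRUE)]
  as.raw(rbind(u1 %% 256L, (u1 %/% 256L) + 16L * (u2 %/% 256L), u2 %% 256L))
}

#' Read a WFDB record
#'
#' Parses the `.hea` header and decodes the signal file.  Formats 16
#' (16-bit little-endian) and 212 (packed 12-bit, as in the MIT-BIH
#' databases) are supported; all signals must live in a single signal
#' file (the MIT-BIH layout).
#'
#' @param record record path with or without the `.hea` extension.
#' @param channel 1-based signal index.
#' @return list with `samples` (ADC integers of the selected channel),
#'   `fs`, `record_name`, `n_channels`, `descriptions`.
#' @export
read_wfdb <- function(record, channel = 1L) {
  base <- sub("\\.hea$", "", record)
  hdr <- parse_wfdb_header(paste0(base, ".hea"))
  if (channel < 1L || channel > hdr$nsig) {
    abort("unknown channel %d: record has %d channel(s): %s", channel,
          hdr$nsig,
          paste(vapply(hdr$signals, `[[`, "", "description"), collapse = ", "))
  }
  files <- unique(vapply(hdr$signals, `[[`, "", "file"))
  if (length(files) != 1L) {
    abort("read_wfdb: multi-file records are not supported")
  }
  fmts <- unique(vapply(hdr$signals, `[[`, 1L, "fmt"))
  if (length(fmts) != 1L || !fmts %in% c(16L, 212L)) {
    abort("read_wfdb: unsupported signal format %s (only 16 and 212)",
          paste(fmts, collapse = ","))
  }
  dat_path <- file.path(dirname(paste0(base, ".hea")), files)
  if (!file.exists(dat_path)) abort("missing file: %s", dat_path)
  raw_bytes <- readBin(dat_path, "raw", n = file.size(dat_path))
  total <- if (is.na(hdr$nsamp)) NA_integer_ else hdr$nsamp * hdr$nsig
  flat <- if (fmts == 16L) {
    v <- readBin(raw_bytes, "integer", n = length(raw_bytes) %/% 2L,
                 size = 2L, signed = TRUE, endian = "little")
    if (!is.na(total)) v[seq_len(min(total, length(v)))] else v
  } else {
    decode_fmt212(raw_bytes, if (is.na(total)) length(raw_bytes) else total)
  }
  nsamp <- length(flat) %/% hdr$nsig
  mat <- matrix(flat[seq_len(nsamp * hdr$nsig)], nrow = hdr$nsig)
  list(samples = as.numeric(mat[channel, ]), fs = hdr$fs,
       record_name = hdr$record_name, n_channels = hdr$nsig,
       descriptions = vapply(hdr$signals, `[[`, "", "description"))
}

#' Write a WFDB record
#'
#' Writes a `.hea`/`.dat` pair in format 16 or 212.  Intended for fixture
#' generation and round-trip testing; samples are rounded to integers.
#'
#' @param samples numeric vector (one channel) or matrix with one row per
#'   channel.
#' @param record_name record name (file stem).
#' @param dir output directory.
#' @param fs sampling rate in Hz.
#' @param fmt 16 or 212.
#' @param gain ADC gain written to the header (metadata only).
#' @param descriptions character vector of channel descriptions.
#' @return the header path invisibly.
#' @export
write_wfdb <- function(samples, record_name, dir, fs, fmt = 16L,
                       gain = 200, descriptions = NULL) {
  if (!is.matrix(samples)) samples <- matrix(samples, nrow = 1L)
  nsig <- nrow(samples)
  nsamp <- ncol(samples)
  fmt <- as.integer(fmt)
  if (!fmt %in% c(16L, 212L)) abort("write_wfdb: fmt must be 16 or 212")
  descriptions <- descriptions %||% sprintf("ECG%d", seq_len(nsig))
  dat_file <- paste0(record_name, ".dat")
  flat <- as.vector(samples)  # column-major = frame-interleaved channels
  s <- as.integer(round(flat))
  if (fmt == 16L) {
    if (any(s < -32768L | s > 32767L)) {
      abort("format 16 stores 16-bit samples: values out of range")
    }
    con <- file(file.path(dir, dat_file), "wb")
    writeBin(s, con, size = 2L, endian = "little")
    close(con)
  } else {
    writeBin(encode_fmt212(s), file.path(dir, dat_file))
  }
  hea <- c(
    sprintf("%s %d %g %d", record_name, nsig, fs, nsamp),
    sprintf("%s %d %g 12 0 0 0 0 %s", dat_file, fmt, gain, descriptions)
  )
  hea_path <- file.path(dir, paste0(record_name, ".hea"))
  writeLines(hea, hea_path)
  invisible(hea_path)
}
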