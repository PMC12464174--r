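## Minimal standard EDF (European Data Format) support: fixed 256-byte ASCII
## header + 256 bytes per signal, then 16-bit little-endian samples scaled
## between the header's physical and digital ranges. Enough of the format for
## multi-channel EEG round trips; EDF+ annotation channels are out of scope.

.edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width, flag = " ")  # left-justified, space padded
}

#' Write an EEG record as a standard 16-bit EDF file
#'
#' All channels share one sampling rate; the whole signal is stored as one
#' EDF data record. Amplitudes are scaled into the 16-bit digital range using
#' a per-channel symmetric physical range, so the round-trip error is bounded
#' by half a quantization step, `(phys_max - phys_min) / 65535 / 2`.
#'
#' @param rec an [eeg_record].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_edf <- function(rec, path) {
  assert(inherits(rec, "eeg_record"), "rec must be an eeg_record")
  ns <- nrow(rec$data)
  n <- ncol(rec$data)
  dig_min <- -32768L
  dig_max <- 32767L
  amp <- apply(abs(rec$data), 1, max)
  amp[amp < .Machine$double.eps] <- 1
  phys_min <- -amp
  phys_max <- amp

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edf_pad("0", 8),
    .edf_pad("X X X X", 80),
    .edf_pad(paste("Startdate 01-JAN-2000", rec$record_id), 80),
    .edf_pad("01.01.00", 8),
    .edf_pad("00.00.00", 8),
    .edf_pad(256L * (1L + ns), 8),
    .edf_pad("", 44),
    .edf_pad(1L, 8),                       # one data record
    .edf_pad(format(n / rec$fs, digits = 7), 8),
    .edf_pad(ns, 4)
  )
  writeChar(hdr, con, eos = NULL)
  fields <- list(
    vapply(rec$channel_labels, .edf_pad, "", width = 16),
    rep(.edf_pad("", 80), ns),
    rep(.edf_pad("uV", 8), ns),
    vapply(phys_min, function(v) .edf_pad(format(v, digits = 7), 8), ""),
    vapply(phys_max, function(v) .edf_pad(format(v, digits = 7), 8), ""),
    rep(.edf_pad(dig_min, 8), ns),
    rep(.edf_pad(dig_max, 8), ns),
    rep(.edf_pad("", 80), ns),
    rep(.edf_pad(n, 8), ns),
    rep(.edf_pad("", 32), ns)
  )
  for (f in fields) writeChar(paste(f, collapse = ""), con, eos = NULL)
  for (ch in seq_len(ns)) {
    scaled <- (rec$data[ch, ] - phys_min[ch]) / (phys_max[ch] - phys_min[ch])
    dig <- as.integer(round(scaled * (dig_max - dig_min) + dig_min))
    dig <- pmin(pmax(dig, dig_min), dig_max)
    writeBin(dig, con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read a standard EDF file into an EEG record
#'
#' Parses the fixed-layout EDF header, loads every signal, and rescales
#' 16-bit digital values into physical units. Channels recorded at different
#' sampling rates are band-limited-resampled to the fastest rate before
#' stacking (with a warning).
#'
#' @param path path to an EDF file.
#' @return an [eeg_record] with channel labels preserved verbatim (trimmed of
#'   the header's space padding).
#' @export
read_edf <- function(path) {
  assert(file.exists(path), sprintf("file not found: %s", path),
         class = "seizr_io_error")
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) readChar(con, width, useBytes = TRUE)
  version <- trimws(rd(8))
  if (!identical(version, "0")) {
    abort(sprintf("not an EDF file (version field '%s')", version),
          "seizr_format_error")
  }
  rd(80); rd(80); rd(8); rd(8)
  header_bytes <- suppressWarnings(as.integer(trimws(rd(8))))
  rd(44)
  n_records <- suppressWarnings(as.integer(trimws(rd(8))))
  duration <- suppressWarnings(as.numeric(trimws(rd(8))))
  ns <- suppressWarnings(as.integer(trimws(rd(4))))
  if (anyNA(c(header_bytes, n_records, duration, ns))) {
    abort("malformed EDF header", "seizr_format_error")
  }
  if (ns < 1L) abort("EDF file contains zero signals", "seizr_empty_input")
  getf <- function(width) vapply(seq_len(ns), function(i) trimws(rd(width)), "")
  labels <- getf(16)
  getf(80)                              # transducer
  getf(8)                               # physical dimension
  phys_min <- as.numeric(getf(8))
  phys_max <- as.numeric(getf(8))
  dig_min <- as.numeric(getf(8))
  dig_max <- as.numeric(getf(8))
  getf(80)                              # prefiltering
  spr <- as.integer(getf(8))            # samples per data record
  getf(32)
  if (anyNA(c(phys_min, phys_max, dig_min, dig_max, spr))) {
    abort("malformed EDF signal header", "seizr_format_error")
  }
  sig <- lapply(seq_len(ns), function(i) numeric(n_records * spr[i]))
  for (r in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[i], size = 2L, signed = TRUE,
                     endian = "little")
      phys <- (dig - dig_min[i]) * (phys_max[i] - phys_min[i]) /
        (dig_max[i] - dig_min[i]) + phys_min[i]
      sig[[i]][(r - 1L) * spr[i] + seq_len(spr[i])] <- phys
    }
  }
  fs_ch <- spr / duration
  fs <- max(fs_ch)
  if (length(unique(fs_ch)) > 1L) {
    warning("heterogeneous per-channel sampling rates; resampling all to max")
    sig <- lapply(seq_len(ns), function(i) {
      if (fs_ch[i] == fs) return(sig[[i]])
      tmp <- eeg_record(matrix(sig[[i]], nrow = 1L), fs_ch[i])
      as.vector(resample_record(tmp, fs)$data)
    })
  }
  n <- max(lengths(sig))
  data <- matrix(0, ns, n)
  for (i in seq_len(ns)) data[i, seq_along(sig[[i]])] <- sig[[i]]
  eeg_record(data, fs, labels,
             record_id = tools::file_path_sans_ext(basename(path)))
}
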