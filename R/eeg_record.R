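#' Construct an EEG record
#'
#' The basic container for a (possibly multi-channel) EEG signal: a
#' channels x samples numeric matrix with its sampling rate, channel labels
#' and optional seizure annotations.
#'
#' @param data numeric matrix, channels x samples (microvolt scale; units are
#'   carried, not enforced).
#' @param fs sampling rate in Hz.
#' @param channel_labels character vector, one label per channel. Defaults to
#'   `"ch1".."chN"`.
#' @param record_id identifier string used in windowing provenance.
#' @param annotations optional data frame with columns `start_s`, `end_s`,
#'   `label` marking annotated intervals (seconds from record start).
#' @return an object of class `eeg_record`.
#' @export
#' @examples
#' rec <- eeg_record(matrix(rnorm(512), nrow = 2), fs = 256)
#' rec
eeg_record <- function(data, fs, channel_labels = NULL, record_id = "rec",
                       annotations = NULL) {
  if (is.vector(data)) data <- matrix(data, nrow = 1L)
  assert(is.matrix(data) && is.numeric(data), "data must be a numeric matrix")
  assert(all(is.finite(data)), "signal contains non-finite values")
  assert(is.numeric(fs) && length(fs) == 1L && fs > 0, "fs must be a positive scalar")
  if (is.null(channel_labels)) channel_labels <- paste0("ch", seq_len(nrow(data)))
  assert(length(channel_labels) == nrow(data),
         "channel_labels length must equal channel count")
  if (!is.null(annotations)) {
    assert(is.data.frame(annotations) &&
             all(c("start_s", "end_s", "label") %in% names(annotations)),
           "annotations must have columns start_s, end_s, label")
    dur <- ncol(data) / fs
    assert(all(annotations$start_s >= 0) && all(annotations$end_s <= dur + 1e-9) &&
             all(annotations$end_s >= annotations$start_s),
           "annotations must lie within [0, duration]")
  }
  structure(
    list(data = data, fs = fs, channel_labels = as.character(channel_labels),
         record_id = as.character(record_id), annotations = annotations),
    class = "eeg_record"
  )
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf("<eeg_record '%s': %d channel(s) x %d samples @ %.2f Hz (%.2f s)>\n",
              x$record_id, nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  if (!is.null(x$annotations)) {
    cat(sprintf("  %d annotation(s): %s\n", nrow(x$annotations),
                paste(unique(x$annotations$label), collapse = ", ")))
  }
  invisible(x)
}

#' @export
dim.eeg_record <- function(x) dim(x$data)

#' Keep the first k channels of a record
#'
#' Multi-channel clinical recordings often carry extra reference or event
#' channels after the montage proper; detection pipelines conventionally keep
#' the leading montage channels (e.g. the first 22 of a 23-channel bipolar
#' montage).
#'
#' @param rec an [eeg_record].
#' @param k number of leading channels to keep (`k <= nrow(rec$data)`).
#' @return an [eeg_record] with the first `k` channels, labels preserved.
#' @export
select_leading_channels <- function(rec, k) {
  assert(inherits(rec, "eeg_record"), "rec must be an eeg_record")
  assert(is_count(k), "k must be a positive integer")
  if (k > nrow(rec$data)) {
    abort(sprintf("k = %d exceeds channel count %d", k, nrow(rec$data)),
          "seizr_bounds_error")
  }
  eeg_record(rec$data[seq_len(k), , drop = FALSE], rec$fs,
             rec$channel_labels[seq_len(k)], rec$record_id, rec$annotations)
}

#' Band-limited resampling of a record to a new sampling rate
#'
#' Polyphase FIR resampling (via [signal::resample]) of every channel, so
#' spectral content below the new Nyquist frequency is preserved. The output
#' sample count is `round(n * target_fs / fs)`.
#'
#' @param rec an [eeg_record].
#' @param target_fs target sampling rate in Hz.
#' @return a resampled [eeg_record] (identity when `target_fs == fs`).
#' @export
resample_record <- function(rec, target_fs) {
  assert(inherits(rec, "eeg_record"), "rec must be an eeg_record")
  assert(is.numeric(target_fs) && length(target_fs) == 1L && target_fs > 0,
         "target_fs must be positive")
  if (isTRUE(all.equal(target_fs, rec$fs))) return(rec)
  n <- ncol(rec$data)
  n_out <- round(n * target_fs / rec$fs)
  # rational approximation of the rate ratio for the polyphase filter
  frac <- .rat_approx(target_fs / rec$fs)
  out <- matrix(0, nrow(rec$data), n_out)
  for (ch in seq_len(nrow(rec$data))) {
    y <- signal::resample(rec$data[ch, ], p = frac[1], q = frac[2])
    if (length(y) >= n_out) {
      out[ch, ] <- y[seq_len(n_out)]
    } else {
      out[ch, seq_along(y)] <- y
    }
  }
  eeg_record(out, target_fs, rec$channel_labels, rec$record_id,
             rec$annotations)
}

# Small continued-fraction rational approximation p/q ~ x.
.rat_approx <- function(x, max_den = 1000L) {
  f <- function(den) c(round(x * den), den)
  best <- f(1L)
  for (den in seq_len(max_den)) {
    cand <- f(den)
    if (abs(cand[1] / cand[2] - x) < abs(best[1] / best[2] - x)) best <- cand
    if (abs(best[1] / best[2] - x) < 1e-9) break
  }
  g <- .gcd(best[1], best[2])
  as.integer(best / g)
}

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)
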