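#' Read a Bonn-style single-channel EEG segment
#'
#' Bonn-style segments are plain-text files with one amplitude sample per
#' line (~4097 samples at 173.61 Hz in the original corpus). Leading and
#' trailing whitespace is tolerated and both integer and float literals are
#' accepted.
#'
#' @param path path to the text file.
#' @param fs sampling rate to attach, Hz (default 173.61).
#' @return a single-channel [eeg_record].
#' @export
read_bonn_segment <- function(path, fs = 173.61) {
  assert(file.exists(path), sprintf("file not found: %s", path),
         class = "seizr_io_error")
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  keep <- nzchar(lines)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    abort(sprintf("empty Bonn segment: %s", path), "seizr_empty_input")
  }
  vals <- suppressWarnings(as.numeric(lines))
  if (anyNA(vals)) {
    bad <- which(keep)[which(is.na(vals))[1]]
    abort(sprintf("unparseable sample at line %d of %s", bad, path),
          "seizr_format_error")
  }
  eeg_record(matrix(vals, nrow = 1L), fs,
             record_id = tools::file_path_sans_ext(basename(path)))
}

#' Write a record as Bonn-style text segments
#'
#' One file per channel, one sample per line. Values are written with enough
#' precision for a lossless text round trip at default numeric precision.
#'
#' @param rec an [eeg_record].
#' @param path output file path for a single-channel record; for multi-channel
#'   records `path` is used as a stem and `_chNN` is appended.
#' @param digits significant digits to write (default 15, i.e. effectively
#'   lossless for doubles stored at plotting scale).
#' @return invisibly, the vector of files written.
#' @export
write_bonn <- function(rec, path, digits = 15) {
  assert(inherits(rec, "eeg_record"), "rec must be an eeg_record")
  nch <- nrow(rec$data)
  files <- if (nch == 1L) {
    path
  } else {
    stem <- tools::file_path_sans_ext(path)
    ext <- tools::file_ext(path)
    if (!nzchar(ext)) ext <- "txt"
    sprintf("%s_ch%02d.%s", stem, seq_len(nch), ext)
  }
  for (ch in seq_len(nch)) {
    writeLines(formatC(rec$data[ch, ], digits = digits, format = "g"),
               files[ch])
  }
  invisible(files)
}

#' Z-score a window per channel
#'
#' Each channel is centred and scaled to zero mean and unit variance
#' (population standard deviation, i.e. divisor `n`). A constant channel has
#' no scale and is mapped to all zeros (with a warning), keeping the output
#' finite.
#'
#' @param w channels x samples numeric matrix (a vector is treated as one
#'   channel).
#' @return matrix of the same shape with per-channel mean 0 and sd 1.
#' @export
normalize_window <- function(w) {
  if (is.vector(w)) w <- matrix(w, nrow = 1L)
  assert(is.matrix(w) && all(is.finite(w)), "window must be a finite matrix")
  n <- ncol(w)
  m <- rowMeans(w)
  centred <- w - m
  s <- sqrt(rowSums(centred^2) / n)
  const <- s <= .Machine$double.eps * pmax(1, abs(m))
  if (any(const)) {
    warning("constant channel(s) mapped to zeros during normalization")
    s[const] <- 1
    centred[const, ] <- 0
  }
  centred / s
}

#' Construct a windowed dataset
#'
#' Fixed-shape windows plus integer class labels and provenance
#' (which record and sample offset each window came from).
#'
#' @param windows list of channels x samples matrices, all the same shape.
#' @param labels integer class ids in `[0, n_classes)`, one per window.
#' @param class_names character vector naming the classes (index `i + 1`
#'   names class id `i`).
#' @param provenance data frame with columns `record_id`, `start_sample`
#'   (0-based offset), one row per window.
#' @param fs sampling rate of the windows, Hz.
#' @param normalized logical: have the windows been z-scored per channel?
#' @return an object of class `windowed_dataset`.
#' @export
windowed_dataset <- function(windows, labels, class_names, provenance, fs,
                             normalized = FALSE) {
  assert(is.list(windows) && length(windows) >= 1L, "windows must be a non-empty list")
  shp <- dim(windows[[1]])
  assert(all(vapply(windows, function(w) identical(dim(w), shp), logical(1))),
         "all windows must share one shape")
  labels <- as.integer(labels)
  assert(length(labels) == length(windows), "one label per window required")
  assert(all(labels >= 0L & labels < length(class_names)),
         "labels must lie in [0, n_classes)")
  assert(is.data.frame(provenance) &&
           all(c("record_id", "start_sample") %in% names(provenance)) &&
           nrow(provenance) == length(windows),
         "provenance must have a row per window")
  structure(
    list(windows = windows, labels = labels,
         class_names = as.character(class_names),
         provenance = provenance, fs = fs, normalized = isTRUE(normalized)),
    class = "windowed_dataset"
  )
}

#' @export
print.windowed_dataset <- function(x, ...) {
  shp <- dim(x$windows[[1]])
  tab <- table(factor(x$class_names[x$labels + 1L], levels = x$class_names))
  cat(sprintf("<windowed_dataset: %d windows of %d ch x %d samples @ %g Hz%s>\n",
              length(x$windows), shp[1], shp[2], x$fs,
              if (x$normalized) ", z-scored" else ""))
  cat("  classes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.windowed_dataset <- function(x) length(x$windows)

#' Cut a record into fixed-length windows
#'
#' Windows are half-open sample ranges `[start, start + window_samples)` laid
#' out left to right with the given overlap; a trailing partial window is
#' dropped. Each window is labeled from the record's annotations by majority
#' overlap (the label covering the largest part of the window wins; a tie is
#' resolved in favour of the seizure class, the safety-conservative choice).
#' Samples not covered by any annotation count as `background`.
#'
#' @param rec an [eeg_record].
#' @param window_samples window length in samples.
#' @param overlap_samples overlap between consecutive windows (default 0;
#'   must be `< window_samples`).
#' @param class_names class name vector; annotation labels are matched
#'   against it. Default `c("background", "seizure")`.
#' @param normalize z-score each window per channel (default TRUE).
#' @return a [windowed_dataset].
#' @export
window_record <- function(rec, window_samples, overlap_samples = 0,
                          class_names = c("background", "seizure"),
                          normalize = TRUE) {
  assert(inherits(rec, "eeg_record"), "rec must be an eeg_record")
  assert(is_count(window_samples), "window_samples must be a positive integer")
  assert(is.numeric(overlap_samples) && overlap_samples >= 0 &&
           overlap_samples == floor(overlap_samples), "overlap must be a non-negative integer")
  if (overlap_samples >= window_samples) {
    abort("overlap_samples must be smaller than window_samples",
          "seizr_invalid_config")
  }
  n <- ncol(rec$data)
  assert(window_samples <= n, "window_samples exceeds record length")
  step <- as.integer(window_samples - overlap_samples)
  n_win <- as.integer(floor((n - window_samples) / step) + 1L)
  starts <- (seq_len(n_win) - 1L) * step  # 0-based
  windows <- vector("list", n_win)
  labels <- integer(n_win)
  for (i in seq_len(n_win)) {
    idx <- (starts[i] + 1L):(starts[i] + window_samples)
    w <- rec$data[, idx, drop = FALSE]
    windows[[i]] <- if (normalize) normalize_window(w) else w
    labels[i] <- .label_window(rec, starts[i], window_samples, class_names)
  }
  windowed_dataset(
    windows, labels, class_names,
    data.frame(record_id = rec$record_id, start_sample = starts,
               stringsAsFactors = FALSE),
    rec$fs, normalized = normalize
  )
}

# Majority-overlap labeling of [start, start+W) (0-based samples) against the
# record's annotations; ties break toward the highest class id (seizure-safe).
.label_window <- function(rec, start, W, class_names) {
  if (is.null(rec$annotations) || nrow(rec$annotations) == 0L) return(0L)
  fs <- rec$fs
  w0 <- start
  w1 <- start + W
  cover <- numeric(length(class_names))
  names(cover) <- class_names
  for (j in seq_len(nrow(rec$annotations))) {
    a <- rec$annotations[j, ]
    a0 <- floor(a$start_s * fs)
    a1 <- floor(a$end_s * fs)
    ov <- max(0, min(w1, a1) - max(w0, a0))
    if (ov > 0 && a$label %in% class_names) {
      cover[[a$label]] <- cover[[a$label]] + ov
    }
  }
  cover[[1L]] <- cover[[1L]] + (W - sum(cover))  # uncovered samples -> background
  best <- max(cover)
  # which classes achieve the maximum; pick the last (highest id) on ties
  cand <- which(cover == best)
  as.integer(max(cand) - 1L)
}

#' Stack a windowed dataset into a feature-ready array
#'
#' @param ds a [windowed_dataset].
#' @return list with `x` (n x channels x samples array) and `y` (labels).
#' @keywords internal
dataset_array <- function(ds) {
  shp <- dim(ds$windows[[1]])
  x <- array(0, dim = c(length(ds$windows), shp[1], shp[2]))
  for (i in seq_along(ds$windows)) x[i, , ] <- ds$windows[[i]]
  list(x = x, y = ds$labels)
}
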