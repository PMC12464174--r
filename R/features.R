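#' Per-channel DWT features concatenated into the model's 1D input vector
#'
#' Each channel of the window is decomposed independently; within a channel
#' the coefficient arrays are laid out coarse to fine (`A_L, D_L, ..., D_1`),
#' and channels are concatenated in channel order. A band map records, for
#' every index of the concatenated vector, its channel, sub-band label and
#' nominal frequency range (at level `l`, detail `D_l` covers
#' `fs/2^(l+1) .. fs/2^l` Hz; the approximation covers `0 .. fs/2^(L+1)`).
#'
#' @param rec_window channels x samples numeric matrix (typically a z-scored
#'   window) or a vector for a single channel.
#' @param cfg a [wavelet_config].
#' @param fs sampling rate in Hz (used only for the band map; default 256).
#' @return an object of class `wavelet_features` with fields `per_channel`
#'   (list over channels of named coefficient lists), `concat` (the 1D
#'   feature vector) and `band_map` (data frame).
#' @export
#' @examples
#' w <- matrix(rnorm(2 * 256), nrow = 2)
#' f <- concat_features(w, wavelet_config("db1", 3))
#' length(f$concat)  # 2 * (32 + 32 + 64 + 128) = 512
concat_features <- function(rec_window, cfg = wavelet_config(), fs = 256) {
  if (is.vector(rec_window)) rec_window <- matrix(rec_window, nrow = 1L)
  nch <- nrow(rec_window)
  per_channel <- vector("list", nch)
  for (ch in seq_len(nch)) {
    per_channel[[ch]] <- dwt_decompose(rec_window[ch, ], cfg)
  }
  band_len <- lengths(per_channel[[1]])
  band_names <- names(per_channel[[1]])
  concat <- unlist(lapply(per_channel, function(b) unlist(b, use.names = FALSE)),
                   use.names = FALSE)
  # nominal band edges per entry of band_names: A_L then D_L .. D_1
  levels_of <- c(cfg$level, rev(seq_len(cfg$level)))
  band_lo <- c(0, fs / 2^(levels_of[-1] + 1))
  band_hi <- c(fs / 2^(cfg$level + 1), fs / 2^levels_of[-1])
  per_len <- sum(band_len)
  band_map <- data.frame(
    index = seq_len(nch * per_len),
    channel = rep(seq_len(nch), each = per_len),
    band = rep(rep(band_names, times = band_len), times = nch),
    band_lo_hz = rep(rep(band_lo, times = band_len), times = nch),
    band_hi_hz = rep(rep(band_hi, times = band_len), times = nch),
    stringsAsFactors = FALSE
  )
  structure(list(per_channel = per_channel, concat = concat,
                 band_map = band_map, config = cfg, fs = fs),
            class = "wavelet_features")
}

#' @export
print.wavelet_features <- function(x, ...) {
  cat(sprintf("<wavelet_features: %d channel(s), %s level %d, concat length %d>\n",
              length(x$per_channel), x$config$wavelet_name, x$config$level,
              length(x$concat)))
  invisible(x)
}

#' Feature matrix for a whole dataset
#'
#' Applies [concat_features] to every window and stacks the concatenated
#' vectors row-wise; the feature extraction is stateless per window, so no
#' information leaks across cross-validation folds.
#'
#' @param ds a [windowed_dataset].
#' @param cfg a [wavelet_config]; `NULL` means raw windows flattened
#'   channel-major (the "without DWT" geometry).
#' @return list with `x` (n x p feature matrix) and `y` (integer labels).
#' @export
featurize_dataset <- function(ds, cfg = wavelet_config()) {
  assert(inherits(ds, "windowed_dataset"), "ds must be a windowed_dataset")
  if (is.null(cfg)) {
    x <- t(vapply(ds$windows, function(w) as.vector(t(w)),
                  numeric(nrow(ds$windows[[1]]) * ncol(ds$windows[[1]]))))
  } else {
    p <- nrow(ds$windows[[1]]) *
      sum(coeff_length(ncol(ds$windows[[1]]), cfg$filter_length, cfg$level))
    x <- t(vapply(ds$windows,
                  function(w) concat_features(w, cfg, ds$fs)$concat,
                  numeric(p)))
  }
  list(x = x, y = ds$labels)
}

#' Time-domain summary features
#'
#' Mean, standard deviation (population) and root-mean-square amplitude per
#' channel; for a z-scored window these describe residual structure, for raw
#' windows they capture amplitude/energy.
#'
#' @param window channels x samples matrix (or vector).
#' @return numeric vector `c(mean_1, sd_1, rms_1, mean_2, ...)` of length
#'   `3 * n_channels`.
#' @export
time_domain_features <- function(window) {
  if (is.vector(window)) window <- matrix(window, nrow = 1L)
  assert(all(is.finite(window)), "window must be finite")
  n <- ncol(window)
  m <- rowMeans(window)
  s <- sqrt(rowSums((window - m)^2) / n)
  rms <- sqrt(rowSums(window^2) / n)
  out <- as.vector(rbind(m, s, rms))
  names(out) <- as.vector(rbind(
    paste0("mean_ch", seq_len(nrow(window))),
    paste0("sd_ch", seq_len(nrow(window))),
    paste0("rms_ch", seq_len(nrow(window)))
  ))
  out
}

#' Welch power spectral density
#'
#' Averaged modified periodograms: the signal is cut into
#' half-overlapping Hann-windowed segments, each periodogram is computed by
#' FFT, and the periodograms are averaged.
#'
#' @param x numeric vector.
#' @param fs sampling rate, Hz.
#' @param nperseg segment length (default `min(256, length(x))`).
#' @return list with `freq` (Hz, one-sided) and `psd`.
#' @export
welch_psd <- function(x, fs, nperseg = min(256L, length(x))) {
  assert(length(x) >= nperseg && nperseg >= 8,
         "signal shorter than the Welch segment length")
  step <- max(1L, floor(nperseg / 2))
  starts <- seq(1L, length(x) - nperseg + 1L, by = step)
  win <- 0.5 - 0.5 * cos(2 * pi * seq(0, nperseg - 1) / nperseg)  # Hann
  scale <- fs * sum(win^2)
  nfreq <- floor(nperseg / 2) + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    seg <- (seg - mean(seg)) * win
    spec <- abs(stats::fft(seg))^2 / scale
    p <- spec[seq_len(nfreq)]
    # double the power of the non-unique (interior) frequencies
    if (nperseg %% 2 == 0) {
      p[2:(nfreq - 1L)] <- 2 * p[2:(nfreq - 1L)]
    } else {
      p[2:nfreq] <- 2 * p[2:nfreq]
    }
    acc <- acc + p
  }
  list(freq = (seq_len(nfreq) - 1L) * fs / nperseg, psd = acc / length(starts))
}

#' Frequency-domain summary features
#'
#' Spectral mean frequency (PSD-weighted centroid) and median frequency (the
#' frequency splitting the cumulative PSD at 50%) per channel, from the Welch
#' spectrum.
#'
#' @param window channels x samples matrix (or vector).
#' @param fs sampling rate, Hz.
#' @param nperseg Welch segment length (default `min(256, n_samples)`).
#' @return numeric vector `c(meanfreq_1, medfreq_1, meanfreq_2, ...)`.
#' @export
freq_domain_features <- function(window, fs, nperseg = NULL) {
  if (is.vector(window)) window <- matrix(window, nrow = 1L)
  if (is.null(nperseg)) nperseg <- min(256L, ncol(window))
  out <- numeric(0)
  for (ch in seq_len(nrow(window))) {
    w <- welch_psd(window[ch, ], fs, nperseg)
    tot <- sum(w$psd)
    mean_f <- if (tot > 0) sum(w$freq * w$psd) / tot else 0
    med_f <- if (tot > 0) w$freq[which(cumsum(w$psd) >= tot / 2)[1]] else 0
    out <- c(out, mean_f, med_f)
  }
  names(out) <- as.vector(rbind(
    paste0("meanfreq_ch", seq_len(nrow(window))),
    paste0("medfreq_ch", seq_len(nrow(window)))
  ))
  out
}

#' Per-window baseline features for classical classifiers
#'
#' @param ds a [windowed_dataset].
#' @param kind `"time"` (mean/sd/RMS) or `"freq"` (mean/median frequency).
#' @return list with `x` (feature matrix) and `y` (labels).
#' @export
summary_features <- function(ds, kind = c("time", "freq")) {
  kind <- match.arg(kind)
  f <- switch(kind,
    time = function(w) time_domain_features(w),
    freq = function(w) freq_domain_features(w, ds$fs)
  )
  rows <- lapply(ds$windows, f)
  list(x = do.call(rbind, rows), y = ds$labels)
}
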