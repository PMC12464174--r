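#' Specification for the synthetic EEG generator
#'
#' The generator emulates the gross spectral structure of scalp EEG in two
#' regimes. Background activity is 1/f ("pink") broadband noise plus an
#' alpha-band oscillation. Seizure-like activity adds a periodic ~3 Hz
#' spike-and-wave discharge and elevated gamma-band power, the two
#' signatures the detector's low-frequency approximation band and gamma
#' detail band are expected to pick up. No claim of physiological seizure
#' morphology is made.
#'
#' @param n_records number of records to generate.
#' @param n_channels channels per record.
#' @param n_samples samples per record (>= 8).
#' @param fs sampling rate, Hz.
#' @param seizure_fraction proportion of seizure-labeled records in `[0, 1]`.
#' @param background_params list: `pink_exponent` (spectral slope, default 1),
#'   `pink_amp` (broadband RMS amplitude, default 1), `alpha_hz` (default 10),
#'   `alpha_amp` (default 1).
#' @param seizure_params list: `spike_rate_hz` (default 3), `spike_amp`
#'   (spike-wave burst amplitude, default 4), `gamma_hz` (default 45),
#'   `gamma_amp` (default 2).
#' @param noise_sd white measurement-noise standard deviation (default 0.5).
#' @param seed master integer seed; per-record seeds are derived by a counter
#'   scheme ([derive_seed]) so any record is individually reproducible.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_records = 100L, n_channels = 1L,
                           n_samples = 256L, fs = 256,
                           seizure_fraction = 0.5,
                           background_params = list(),
                           seizure_params = list(),
                           noise_sd = 0.5, seed = 1L) {
  assert(is_count(n_records) && is_count(n_channels), "counts must be positive integers")
  assert(is_count(n_samples) && n_samples >= 8, "n_samples must be >= 8")
  assert(is.numeric(fs) && fs > 0, "fs must be positive")
  assert(is.numeric(seizure_fraction) && seizure_fraction >= 0 &&
           seizure_fraction <= 1, "seizure_fraction must lie in [0, 1]")
  bg <- utils::modifyList(
    list(pink_exponent = 1, pink_amp = 1, alpha_hz = 10, alpha_amp = 1),
    background_params
  )
  sz <- utils::modifyList(
    list(spike_rate_hz = 3, spike_amp = 4, gamma_hz = 45, gamma_amp = 2),
    seizure_params
  )
  structure(list(n_records = as.integer(n_records),
                 n_channels = as.integer(n_channels),
                 n_samples = as.integer(n_samples), fs = fs,
                 seizure_fraction = seizure_fraction,
                 background_params = bg, seizure_params = sz,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_spec")
}

# 1/f^exponent noise with unit RMS, via spectral shaping of white noise.
.pink_noise <- function(n, exponent) {
  nf <- n %/% 2
  mag <- (seq_len(nf))^(-exponent / 2)
  re <- stats::rnorm(nf) * mag
  im <- stats::rnorm(nf) * mag
  spec <- complex(real = re, imaginary = im)
  full <- complex(length.out = n)
  full[2:(nf + 1)] <- spec
  full[n:(n - nf + 2)] <- Conj(spec[seq_len(nf - 1L)])
  x <- Re(stats::fft(full, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

# Periodic spike-and-wave waveform: a slow sawtooth "wave" with a sharp
# Gaussian "spike" riding on each cycle; unit peak amplitude.
.spike_wave <- function(t, rate_hz) {
  phase <- (t * rate_hz) %% 1
  saw <- 0.5 * (1 - 2 * abs(phase - 0.5) * 2)       # triangular wave in [-0.5, 0.5]
  spike <- exp(-((phase - 0.2)^2) / (2 * 0.02^2))   # narrow spike each cycle
  saw + spike
}

#' Generate one synthetic EEG record
#'
#' Background regime: pink noise + alpha sinusoid (+ white noise). Seizure
#' regime additionally carries a periodic spike-wave discharge at
#' `spike_rate_hz` and a gamma-band sinusoid. Oscillatory phase is shared
#' across channels up to a small random jitter; broadband and white noise are
#' independent per channel. Bit-identical output under a fixed seed.
#'
#' @param spec a [synthetic_spec].
#' @param label `"background"` or `"seizure"`.
#' @param seed integer seed for this record (defaults to `spec$seed`).
#' @param record_id identifier attached to the record.
#' @return an [eeg_record] of shape `n_channels x n_samples`.
#' @export
generate_record <- function(spec, label = c("background", "seizure"),
                            seed = spec$seed, record_id = NULL) {
  assert(inherits(spec, "synthetic_spec"), "spec must be a synthetic_spec")
  label <- match.arg(label)
  if (is.null(record_id)) record_id <- sprintf("sim_%s_%d", label, seed)
  bg <- spec$background_params
  sz <- spec$seizure_params
  n <- spec$n_samples
  t <- (seq_len(n) - 1L) / spec$fs
  with_seed(seed, {
    base_phase <- stats::runif(1, 0, 2 * pi)
    data <- matrix(0, spec$n_channels, n)
    for (ch in seq_len(spec$n_channels)) {
      jitter <- stats::rnorm(1, 0, 0.1)
      x <- bg$alpha_amp * sin(2 * pi * bg$alpha_hz * t + base_phase + jitter)
      if (bg$pink_amp > 0) {
        x <- x + bg$pink_amp * .pink_noise(n, bg$pink_exponent)
      }
      if (label == "seizure") {
        x <- x + sz$spike_amp * .spike_wave(t + jitter / (2 * pi), sz$spike_rate_hz) +
          sz$gamma_amp * sin(2 * pi * sz$gamma_hz * t + base_phase + jitter)
      }
      if (spec$noise_sd > 0) {
        x <- x + stats::rnorm(n, 0, spec$noise_sd)
      }
      data[ch, ] <- x
    }
    eeg_record(data, spec$fs, record_id = record_id)
  })
}

#' Generate a labeled synthetic dataset
#'
#' `round(seizure_fraction * n_records)` records carry the seizure label; the
#' class sequence is a seed-determined shuffle, and record `i` is generated
#' from the derived seed `derive_seed(seed, i)`, so the whole dataset and any
#' single record are reproducible. Each record becomes one window.
#'
#' @param spec a [synthetic_spec].
#' @param normalize z-score each window per channel (default TRUE, the form
#'   the classifier consumes).
#' @return a [windowed_dataset] with classes `background`/`seizure`.
#' @export
generate_dataset <- function(spec, normalize = TRUE) {
  assert(inherits(spec, "synthetic_spec"), "spec must be a synthetic_spec")
  n_seiz <- round(spec$seizure_fraction * spec$n_records)
  labels <- c(rep(1L, n_seiz), rep(0L, spec$n_records - n_seiz))
  labels <- with_seed(spec$seed, sample(labels))
  class_names <- c("background", "seizure")
  windows <- vector("list", spec$n_records)
  for (i in seq_len(spec$n_records)) {
    rec <- generate_record(spec, class_names[labels[i] + 1L],
                           seed = derive_seed(spec$seed, i),
                           record_id = sprintf("sim_%04d", i))
    windows[[i]] <- if (normalize) normalize_window(rec$data) else rec$data
  }
  windowed_dataset(
    windows, labels, class_names,
    data.frame(record_id = sprintf("sim_%04d", seq_len(spec$n_records)),
               start_sample = 0L, stringsAsFactors = FALSE),
    spec$fs, normalized = normalize
  )
}

#' Preset generator specs mimicking the benchmark corpora
#'
#' `"bonn"`: single-channel, 4097-sample segments at 173.61 Hz.
#' `"chbmit"`: 22-channel 256 Hz windows. `"tusz"`: 22-channel one-second
#' (256-sample) windows at 256 Hz.
#'
#' @param preset one of `"bonn"`, `"chbmit"`, `"tusz"`.
#' @param ... overrides passed to [synthetic_spec].
#' @return a [synthetic_spec].
#' @export
synthetic_preset <- function(preset = c("bonn", "chbmit", "tusz"), ...) {
  preset <- match.arg(preset)
  args <- switch(preset,
    bonn   = list(n_channels = 1L, n_samples = 4097L, fs = 173.61),
    chbmit = list(n_channels = 22L, n_samples = 256L, fs = 256),
    tusz   = list(n_channels = 22L, n_samples = 256L, fs = 256)
  )
  do.call(synthetic_spec, utils::modifyList(args, list(...)))
}
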