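test_that("generation is bit-reproducible under a fixed seed", {
  spec <- synthetic_spec(n_records = 6L, n_channels = 3L, n_samples = 128L,
                         seed = 42L)
  a <- generate_record(spec, "seizure", seed = 7L)
  b <- generate_record(spec, "seizure", seed = 7L)
  expect_identical(a$data, b$data)
  c <- generate_record(spec, "seizure", seed = 8L)
  expect_false(identical(a$data, c$data))
  d1 <- generate_dataset(spec)
  d2 <- generate_dataset(spec)
  expect_identical(d1$windows, d2$windows)
  expect_identical(d1$labels, d2$labels)
})

test_that("a noiseless pure alpha record peaks at the alpha frequency", {
  spec <- synthetic_spec(n_channels = 1L, n_samples = 512L, fs = 256,
                         background_params = list(pink_amp = 0, alpha_hz = 10),
                         noise_sd = 0, seed = 1L)
  rec <- generate_record(spec, "background", seed = 3L)
  w <- welch_psd(rec$data[1, ], 256, nperseg = 256)
  peak <- w$freq[which.max(w$psd)]
  expect_lte(abs(peak - 10), 256 / 256)  # within one frequency bin
})

test_that("preset geometries match the corpora they emulate", {
  bonn <- generate_record(synthetic_preset("bonn", seed = 2L), "background")
  expect_identical(dim(bonn), c(1L, 4097L))
  expect_equal(bonn$fs, 173.61)
  tusz <- generate_dataset(synthetic_preset("tusz", n_records = 4L, seed = 2L))
  for (w in tusz$windows) expect_identical(dim(w), c(22L, 256L))
  expect_equal(tusz$fs, 256)
})

test_that("label counts follow the seizure fraction exactly", {
  ds <- generate_dataset(synthetic_spec(n_records = 100L, n_samples = 64L,
                                        seizure_fraction = 0.2, seed = 5L))
  expect_identical(sum(ds$labels == 1L), 20L)
  ds0 <- generate_dataset(synthetic_spec(n_records = 10L, n_samples = 64L,
                                         seizure_fraction = 0, seed = 5L))
  expect_true(all(ds0$labels == 0L))
})

test_that("seizure records carry more relative gamma-band power", {
  spec <- synthetic_spec(n_channels = 1L, n_samples = 256L, fs = 256,
                         seed = 100L)
  ratio <- function(label, seed) {
    x <- generate_record(spec, label, seed = seed)$data[1, ]
    periodogram_band_power(x, 256, 32, 64) /
      periodogram_band_power(x, 256, 0, 16)
  }
  n <- 40L
  r_bg <- vapply(seq_len(n), function(i) ratio("background", 200 + i), 0)
  r_sz <- vapply(seq_len(n), function(i) ratio("seizure", 200 + i), 0)
  expect_gt(mean(r_sz), mean(r_bg))
})

test_that("the class gap closes as seizure amplitudes approach background", {
  gap <- function(amp) {
    spec <- synthetic_spec(n_channels = 1L, n_samples = 256L, fs = 256,
                           seizure_params = list(spike_amp = amp,
                                                 gamma_amp = amp / 2),
                           seed = 9L)
    bp <- function(label, seed) {
      x <- generate_record(spec, label, seed = seed)$data[1, ]
      periodogram_band_power(x, 256, 32, 64)
    }
    mean(vapply(1:20, function(i) bp("seizure", 300 + i), 0)) -
      mean(vapply(1:20, function(i) bp("background", 300 + i), 0))
  }
  gaps <- vapply(c(4, 1, 0), gap, 0)
  expect_true(all(diff(gaps) < 0))
  expect_lt(abs(gaps[3]), abs(gaps[1]) / 10)
})

test_that("invalid generator specs are rejected", {
  expect_error(synthetic_spec(n_records = 0L), class = "seizr_invalid_input")
  expect_error(synthetic_spec(n_samples = 4L), class = "seizr_invalid_input")
  expect_error(synthetic_spec(seizure_fraction = 1.2),
               class = "seizr_invalid_input")
})

test_that("generated windows satisfy the dataset validation rules", {
  ds <- generate_dataset(synthetic_spec(n_records = 8L, n_channels = 2L,
                                        n_samples = 128L, seed = 3L))
  expect_s3_class(ds, "windowed_dataset")
  for (w in ds$windows) {
    expect_true(all(is.finite(w)))
    expect_lt(max(abs(rowMeans(w))), 1e-6)
    expect_lt(max(abs(sqrt(rowMeans(w^2)) - 1)), 1e-6)  # mean 0 so rms = sd
  }
})
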