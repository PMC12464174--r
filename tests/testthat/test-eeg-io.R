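test_that("Bonn-style text segments read back with the right shape", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(as.character(round(rnorm(4097) * 100)), path)
  rec <- read_bonn_segment(path)
  expect_identical(dim(rec), c(1L, 4097L))
  expect_equal(rec$fs, 173.61)

  writeLines("0", path)
  one <- read_bonn_segment(path)
  expect_identical(dim(one), c(1L, 1L))
  expect_identical(one$data[1, 1], 0)
})

test_that("malformed and empty Bonn files raise classed errors", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("1", "2", "oops", "4"), path)
  err <- tryCatch(read_bonn_segment(path), error = identity)
  expect_s3_class(err, "seizr_format_error")
  expect_match(conditionMessage(err), "line 3")
  writeLines(character(0), path)
  expect_error(read_bonn_segment(path), class = "seizr_empty_input")
})

test_that("Bonn write/read round trip preserves the signal", {
  spec <- synthetic_preset("bonn", seed = 4L)
  rec <- generate_record(spec, "seizure", seed = 4L)
  path <- withr::local_tempfile(fileext = ".txt")
  write_bonn(rec, path)
  back <- read_bonn_segment(path, fs = spec$fs)
  expect_equal(back$data, rec$data, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("leading-channel selection keeps order, labels and bounds", {
  rec <- eeg_record(matrix(rnorm(23 * 64), 23), fs = 256,
                    channel_labels = paste0("C", 1:23))
  r22 <- select_leading_channels(rec, 22L)
  expect_identical(nrow(r22$data), 22L)
  expect_identical(r22$channel_labels, paste0("C", 1:22))
  expect_identical(select_leading_channels(rec, 23L)$data, rec$data)
  r3 <- eeg_record(matrix(1:12, 3, byrow = TRUE), fs = 1)
  expect_identical(select_leading_channels(r3, 1L)$data,
                   r3$data[1, , drop = FALSE])
  expect_error(select_leading_channels(r3, 4L), class = "seizr_bounds_error")
})

test_that("resampling halves counts, keeps tones, and is identity at fs", {
  rec <- eeg_record(matrix(rnorm(1024), 1), fs = 512)
  half <- resample_record(rec, 256)
  expect_identical(ncol(half$data), 512L)
  expect_equal(half$fs, 256)

  t <- (0:2499) / 500
  tone <- eeg_record(matrix(sin(2 * pi * 10 * t), 1), fs = 500)
  res <- resample_record(tone, 256)
  w <- welch_psd(res$data[1, ], 256, nperseg = 256)
  expect_lte(abs(w$freq[which.max(w$psd)] - 10), 256 / 256)

  expect_identical(resample_record(rec, 512)$data, rec$data)
})

test_that("windowing counts, labeling and provenance follow the rules", {
  rec <- eeg_record(matrix(rnorm(2560), 1), fs = 256)
  ds <- window_record(rec, 256L)
  expect_length(ds, 10L)
  ds2 <- window_record(eeg_record(matrix(rnorm(2570), 1), fs = 256), 256L)
  expect_length(ds2, 10L)  # trailing partial window dropped

  ann <- data.frame(start_s = 1, end_s = 2, label = "seizure")
  rec_a <- eeg_record(matrix(rnorm(256 * 4), 1), fs = 256, annotations = ann)
  ds3 <- window_record(rec_a, 256L)
  expect_identical(ds3$labels, c(0L, 1L, 0L, 0L))

  expect_error(window_record(rec, 256L, overlap_samples = 256L),
               class = "seizr_invalid_config")

  # provenance offsets tile the consumed prefix disjointly at zero overlap
  expect_identical(ds$provenance$start_sample, seq(0L, 2304L, by = 256L))
})

test_that("half-covered windows break ties toward the seizure class", {
  ann <- data.frame(start_s = 0.5, end_s = 1.5, label = "seizure")
  rec <- eeg_record(matrix(rnorm(512), 1), fs = 256, annotations = ann)
  ds <- window_record(rec, 256L)
  expect_identical(ds$labels, c(1L, 1L))  # each window is exactly half seizure
})

test_that("z-scoring is exact, degenerate-safe and idempotent", {
  z <- normalize_window(matrix(c(1, 2, 3), 1))
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(z^2)), 1, tolerance = 1e-12)

  expect_warning(zc <- normalize_window(matrix(5, 1, 3)))
  expect_identical(as.vector(zc), c(0, 0, 0))

  w <- matrix(rnorm(4 * 100, sd = 7, mean = 3), 4)
  z1 <- normalize_window(w)
  expect_equal(normalize_window(z1), z1, tolerance = 1e-10)
  expect_identical(dim(z1), dim(w))
})
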