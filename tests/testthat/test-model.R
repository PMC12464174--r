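table2_lengths <- c(2050L, 2050L, 2050L, 1025L, 1025L, 1025L, 512L, 512L,
                    512L, 255L, 255L, 255L, 255L, 127L, 127L, 127L, 127L,
                    63L, 63L, 63L, 63L, 31L, 1L, 1L, 1L, 1L, 1L, 1L)
table2_channels <- c(16L, 16L, 16L, 32L, 32L, 32L, 64L, 64L, 64L, 64L, 128L,
                     128L, 128L, 128L, 256L, 256L, 256L, 256L, 512L, 512L,
                     512L, 512L, 200L, 200L, 64L, 64L, 1L, 1L)
table2_params <- c(48, 64, 0, 1056, 128, 0, 4160, 256, 0, 0, 8320, 512, 0, 0,
                   33024, 1024, 0, 0, 131584, 2048, 0, 0, 570400, 0, 12864,
                   0, 65, 0)

test_that("the default architecture reproduces the printed summary exactly", {
  spec <- default_spec(4100L, 2L)
  expect_length(spec$layers, 28L)
  sh <- infer_shapes(spec)
  expect_identical(sh$out_len, table2_lengths)
  expect_identical(sh$out_ch, table2_channels)
  pc <- count_parameters(spec)
  expect_identical(pc$per_layer, table2_params)
  expect_identical(pc$total, 765553)
})

test_that("the head adapts to the class count", {
  spec8 <- default_spec(4100L, 8L)
  expect_identical(spec8$head, "softmax")
  dense_units <- spec8$layers[[27]]$units
  expect_identical(dense_units, 8L)
  expect_identical(default_spec(4100L, 2L)$layers[[27]]$units, 1L)
})

test_that("too-short inputs fail shape inference with a named layer", {
  err <- tryCatch(default_spec(63L, 2L), error = identity)
  expect_s3_class(err, "seizr_shape_error")
  expect_match(conditionMessage(err), "layer \\d+")
})

test_that("valid-padding arithmetic handles unit kernels and pooling", {
  s <- model_spec(255L, list(layer_spec("conv1d", filters = 4L, kernel = 1L,
                                        stride = 1L)), 2L)
  expect_identical(infer_shapes(s)$out_len, 255L)
  p <- model_spec(255L, list(layer_spec("maxpool1d", pool = 3L, stride = 2L)), 2L)
  expect_identical(infer_shapes(p)$out_len, 127L)
})

test_that("built models materialize exactly the counted parameters", {
  spec <- default_spec(4100L, 2L)
  m <- build(spec, seed = 1L)
  expect_identical(model_parameter_count(m), 765553L)

  tiny <- tiny_spec()
  expect_identical(model_parameter_count(build(tiny, seed = 2L)),
                   as.integer(count_parameters(tiny)$total))
})

test_that("softmax outputs normalize and zero-weight sigmoids sit at 0.5", {
  spec <- tiny_spec(n_classes = 3L)
  m <- build(spec, seed = 4L)
  p <- predict(m, matrix(rnorm(4 * 24), 4))
  expect_equal(unname(rowSums(p)), rep(1, 4), tolerance = 1e-6)
  expect_true(all(p >= 0 & p <= 1))

  mz <- build(tiny_spec(), seed = 1L, init = "zeros")
  pz <- predict(mz, matrix(rnorm(5 * 24), 5))
  expect_equal(unname(pz[, 1]), rep(0.5, 5), tolerance = 1e-12)
})

test_that("analytic counts and shapes agree with materialized models", {
  set.seed(77)
  for (trial in 1:15) {
    spec <- random_spec()
    m <- build(spec, seed = trial)
    expect_identical(model_parameter_count(m),
                     as.integer(count_parameters(spec)$total))
    fwd <- seizr:::nn_forward(m, matrix(rnorm(2 * spec$input_length), 2))
    sh <- infer_shapes(spec)
    expect_identical(fwd$shapes[, 1], as.numeric(sh$out_len))
    expect_identical(fwd$shapes[, 2], as.numeric(sh$out_ch))
  }
})

test_that("longer inputs never shrink any intermediate length", {
  sh1 <- infer_shapes(default_spec(1000L, 2L))
  sh2 <- infer_shapes(default_spec(1500L, 2L))
  sh3 <- infer_shapes(default_spec(4100L, 2L))
  expect_true(all(sh2$out_len >= sh1$out_len))
  expect_true(all(sh3$out_len >= sh2$out_len))
})

test_that("model specs survive a JSON round trip", {
  spec <- default_spec(4100L, 2L)
  path <- withr::local_tempfile(fileext = ".json")
  spec_to_json(spec, path)
  back <- spec_from_json(path)
  expect_identical(count_parameters(back)$total, 765553)
  expect_identical(infer_shapes(back), infer_shapes(spec))
})
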