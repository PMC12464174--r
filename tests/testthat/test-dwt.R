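# Reference coefficient values computed once with PyWavelets 1.9.0
# (mode = "symmetric") on the fixed 16-sample fixture below, then frozen.
dwt_fixture <- c(5, 3, 8, 1, 9, 2, 7, 4, 6, 0, 5, 8, 2, 9, 1, 7)

test_that("db1/db2/db3 coefficients match the reference implementation", {
  d1 <- dwt_decompose(dwt_fixture, wavelet_config("db1", 3))
  expect_equal(d1$A3, c(13.788582233138, 13.435028842544), tolerance = 1e-9)
  expect_equal(d1$D3, c(-1.767766952966, 0), tolerance = 1e-9)
  expect_equal(d1$D2, c(-0.5, 0, -3.5, 1.5), tolerance = 1e-9)
  expect_equal(d1$D1,
               c(1.414213562373, 4.949747468306, 4.949747468306,
                 2.121320343560, 4.242640687119, -2.121320343560,
                 -4.949747468306, -4.242640687119), tolerance = 1e-9)

  d2 <- dwt_decompose(dwt_fixture, wavelet_config("db2", 2))
  expect_equal(d2$A2,
               c(9.079246824527, 9.117227771689, 10.457531754731,
                 7.263461894323, 11.324759526419, 10.928525403784),
               tolerance = 1e-9)
  expect_equal(d2$D2,
               c(-0.137259526419, -0.3125, 2.890544456623, 1.532291281150,
                 -0.087019052838, -0.266746824527), tolerance = 1e-9)

  d3 <- dwt_decompose(dwt_fixture, wavelet_config("db3", 1))
  expect_equal(d3$D1,
               c(1.050781800024, 4.600659160199, 5.489172096774,
                 2.549955778016, 2.544681082056, 1.151376141621,
                 -5.522969323614, -5.071060269942, 2.800840526098,
                 5.825043044769), tolerance = 1e-9)

  # odd length exercises the boundary extension
  d4 <- dwt_decompose(c(1, 4, 2, 8, 5, 7, 3), wavelet_config("db1", 2))
  expect_equal(d4$A2, c(7.5, 9), tolerance = 1e-9)
  expect_equal(d4$D2, c(-2.5, 3), tolerance = 1e-9)
  expect_equal(d4$D1, c(-2.121320343560, -4.242640687119, -1.414213562373, 0),
               tolerance = 1e-9)
})

test_that("coefficient lengths follow the iterated halving rule", {
  expect_identical(unname(coeff_length(4097, 2, 3)),
                   c(513L, 513L, 1025L, 2049L))
  expect_identical(sum(coeff_length(4097, 2, 3)), 4100L)
  expect_identical(sum(coeff_length(4097, 6, 3)), 4111L)
  expect_identical(unname(coeff_length(256, 2, 3)), c(32L, 32L, 64L, 128L))

  # property: the closed form matches the actual decomposition lengths
  set.seed(31)
  for (trial in 1:20) {
    n <- sample(50:1000, 1)
    wname <- sample(c("db1", "db2", "db3", "db4"), 1)
    lev <- sample(1:3, 1)
    cfg <- wavelet_config(wname, lev)
    lens <- tryCatch(coeff_length(n, cfg$filter_length, lev),
                     error = function(e) NULL)
    if (is.null(lens)) next
    d <- dwt_decompose(rnorm(n), cfg)
    expect_identical(unname(lengths(d)), unname(as.integer(lens)))
  }
})

test_that("the orthogonal transform conserves energy on dyadic lengths", {
  set.seed(7)
  for (n in c(64, 256, 1024)) {
    x <- rnorm(n)
    d <- dwt_decompose(x, wavelet_config("db1", 3))
    expect_lt(abs(sum(unlist(d)^2) - sum(x^2)) / sum(x^2), 1e-8)
  }
})

test_that("the Haar wavelet annihilates constant signals", {
  d <- dwt_decompose(rep(4.2, 64), wavelet_config("db1", 3))
  expect_identical(max(abs(c(d$D3, d$D2, d$D1))), 0)
})

test_that("infeasible inputs raise classed errors", {
  expect_error(dwt_decompose(c(1, 2, 3), wavelet_config("db3", 1)),
               class = "seizr_invalid_input")   # shorter than the filter
  expect_error(coeff_length(8, 6, 3), class = "seizr_level_error")
  expect_error(wavelet_config("sym4"), class = "seizr_invalid_input")
})
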