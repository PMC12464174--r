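# Shared helpers for the seizr test suite. Fixtures are built in code; no
# binary files are stored.

# A tiny architecture touching every layer kind, for gradient and engine
# tests (input length 24).
tiny_spec <- function(n_classes = 2L, dropout_rate = 0) {
  layers <- list(
    layer_spec("conv1d", filters = 3L, kernel = 2L, stride = 2L),
    layer_spec("batchnorm"),
    layer_spec("relu"),
    layer_spec("maxpool1d", pool = 3L, stride = 2L),
    layer_spec("conv1d", filters = 4L, kernel = 1L, stride = 1L),
    layer_spec("lstm", units = 5L),
    layer_spec("flatten"),
    layer_spec("dense", units = 4L, activation = "relu", l2 = 0.01),
    layer_spec("dropout", rate = dropout_rate),
    layer_spec("dense", units = if (n_classes == 2L) 1L else n_classes),
    layer_spec("activation",
               activation = if (n_classes == 2L) "sigmoid" else "softmax")
  )
  model_spec(24L, layers, n_classes)
}

# Small, cheap architecture for an arbitrary input length (used where the
# test exercises the training machinery rather than the full network).
tiny_spec_for <- function(input_length, n_classes = 2L) {
  layers <- list(
    layer_spec("conv1d", filters = 4L, kernel = 2L, stride = 2L),
    layer_spec("batchnorm"),
    layer_spec("relu"),
    layer_spec("maxpool1d", pool = 3L, stride = 2L),
    layer_spec("lstm", units = 8L),
    layer_spec("flatten"),
    layer_spec("dense", units = 8L, activation = "relu", l2 = 0.01),
    layer_spec("dense", units = if (n_classes == 2L) 1L else n_classes),
    layer_spec("activation",
               activation = if (n_classes == 2L) "sigmoid" else "softmax")
  )
  model_spec(as.integer(input_length), layers, as.integer(n_classes))
}

# Random valid spec in the default architecture's family (conv blocks +
# optional pools, LSTM, dense head) for oracle-equivalence properties.
random_spec <- function() {
  len <- sample(200:600, 1)
  n_classes <- sample(c(2L, 3L), 1)
  layers <- list()
  for (b in seq_len(sample(1:3, 1))) {
    layers <- c(layers, list(
      layer_spec("conv1d", filters = sample(4:16, 1),
                 kernel = sample(1:3, 1), stride = sample(1:2, 1)),
      layer_spec("batchnorm"),
      layer_spec("relu")
    ))
    if (stats::runif(1) < 0.5) {
      layers <- c(layers, list(layer_spec("maxpool1d", pool = sample(2:3, 1),
                                          stride = 2L)))
    }
  }
  layers <- c(layers, list(
    layer_spec("lstm", units = sample(5:20, 1)),
    layer_spec("flatten"),
    layer_spec("dense", units = sample(8:16, 1), activation = "relu",
               l2 = 0.01),
    layer_spec("dropout", rate = 0.2),
    layer_spec("dense", units = if (n_classes == 2L) 1L else n_classes),
    layer_spec("activation",
               activation = if (n_classes == 2L) "sigmoid" else "softmax")
  ))
  model_spec(len, layers, n_classes)
}

# Direct periodogram band power of a single-channel signal: an oracle
# independent of welch_psd (raw squared FFT magnitudes summed over a band).
periodogram_band_power <- function(x, fs, lo, hi) {
  n <- length(x)
  p <- abs(stats::fft(x))^2 / n
  f <- (seq_len(n) - 1) * fs / n
  keep <- f >= lo & f < hi & f <= fs / 2
  sum(p[keep])
}

quiet_cv <- function(...) suppressWarnings(run_cv(...))
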