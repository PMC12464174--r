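#' Single layer descriptor
#'
#' @param kind one of `"conv1d"`, `"batchnorm"`, `"relu"`, `"maxpool1d"`,
#'   `"lstm"`, `"flatten"`, `"dense"`, `"dropout"`, `"activation"`.
#' @param filters,units,kernel,stride,pool,rate,l2,activation layer
#'   hyperparameters; only those relevant to `kind` are used. Padding is
#'   always "valid" (no border padding).
#' @return a `layer_spec` list.
#' @export
layer_spec <- function(kind, filters = NULL, units = NULL, kernel = NULL,
                       stride = NULL, pool = NULL, rate = NULL, l2 = 0,
                       activation = NULL) {
  kinds <- c("conv1d", "batchnorm", "relu", "maxpool1d", "lstm", "flatten",
             "dense", "dropout", "activation")
  assert(kind %in% kinds, sprintf("unknown layer kind '%s'", kind))
  for (v in list(filters, units, kernel, stride, pool)) {
    if (!is.null(v)) assert(is_count(v), "layer counts must be positive integers")
  }
  structure(list(kind = kind, filters = filters, units = units,
                 kernel = kernel, stride = stride, pool = pool, rate = rate,
                 l2 = l2, activation = activation, padding = "valid"),
            class = "layer_spec")
}

#' Full model specification
#'
#' @param input_length length of the 1D input feature vector.
#' @param layers ordered list of [layer_spec] objects.
#' @param n_classes number of classes (2 uses a 1-unit sigmoid head,
#'   otherwise a `n_classes`-unit softmax head).
#' @return a `model_spec` object (shape inference is run to validate it).
#' @export
model_spec <- function(input_length, layers, n_classes = 2L) {
  assert(is_count(input_length), "input_length must be a positive integer")
  assert(is_count(n_classes) && n_classes >= 2, "n_classes must be >= 2")
  spec <- structure(list(input_length = as.integer(input_length),
                         input_channels = 1L, layers = layers,
                         n_classes = as.integer(n_classes),
                         head = if (n_classes == 2L) "sigmoid" else "softmax"),
                    class = "model_spec")
  infer_shapes(spec)  # validates; errors name the failing layer
  spec
}

#' The default 1D CNN-LSTM architecture
#'
#' Six strided valid-padding convolutions (16, 32, 64, 128, 256, 512 filters;
#' the first three with kernel 2 stride 2, the last three with kernel 1
#' stride 1) interleaved with batch normalization, ReLU, and four max-pooling
#' layers (pool 3, stride 2); a single 200-unit LSTM consuming the final
#' feature-map sequence and emitting its last hidden state; then a 64-unit
#' ReLU dense layer with L2(0.03) kernel regularization, 40% dropout, and the
#' classification head (1-unit sigmoid for binary, `n_classes`-unit softmax
#' otherwise). With `input_length = 4100` this stack has exactly 765,553
#' parameters (batch-norm moving statistics included).
#'
#' @param input_length length of the concatenated wavelet feature vector.
#' @param n_classes number of target classes.
#' @return a [model_spec].
#' @export
#' @examples
#' spec <- default_spec(4100, 2)
#' count_parameters(spec)$total  # 765553
default_spec <- function(input_length, n_classes = 2L) {
  head_units <- if (n_classes == 2L) 1L else as.integer(n_classes)
  head_act <- if (n_classes == 2L) "sigmoid" else "softmax"
  layers <- list(
    layer_spec("conv1d", filters = 16L, kernel = 2L, stride = 2L),
    layer_spec("batchnorm"),
    layer_spec("relu"),
    layer_spec("conv1d", filters = 32L, kernel = 2L, stride = 2L),
    layer_spec("batchnorm"),
    layer_spec("relu"),
    layer_spec("conv1d", filters = 64L, kernel = 2L, stride = 2L),
    layer_spec("batchnorm"),
    layer_spec("relu"),
    layer_spec("maxpool1d", pool = 3L, stride = 2L),
    layer_spec("conv1d", filters = 128L, kernel = 1L, stride = 1L),
    layer_spec("batchnorm"),
    layer_spec("relu"),
    layer_spec("maxpool1d", pool = 3L, stride = 2L),
    layer_spec("conv1d", filters = 256L, kernel = 1L, stride = 1L),
    layer_spec("batchnorm"),
    layer_spec("relu"),
    layer_spec("maxpool1d", pool = 3L, stride = 2L),
    layer_spec("conv1d", filters = 512L, kernel = 1L, stride = 1L),
    layer_spec("batchnorm"),
    layer_spec("relu"),
    layer_spec("maxpool1d", pool = 3L, stride = 2L),
    layer_spec("lstm", units = 200L),
    layer_spec("flatten"),
    layer_spec("dense", units = 64L, activation = "relu", l2 = 0.03),
    layer_spec("dropout", rate = 0.4),
    layer_spec("dense", units = head_units),
    layer_spec("activation", activation = head_act)
  )
  model_spec(input_length, layers, n_classes)
}

#' Per-layer output shapes
#'
#' Valid-padding rule for convolution and pooling:
#' `out = floor((in - k) / s) + 1`. Batch norm, ReLU, dropout and the head
#' activation preserve shape; the LSTM collapses the sequence to its final
#' hidden state `(units,)`; flatten merges length and channels.
#'
#' @param spec a [model_spec].
#' @return data frame with one row per layer: `layer`, `kind`, `out_len`,
#'   `out_ch` (so Table-style "(len, ch)" output shapes can be printed).
#' @export
infer_shapes <- function(spec) {
  len <- as.integer(spec$input_length)
  ch <- as.integer(spec$input_channels)
  rows <- vector("list", length(spec$layers))
  for (i in seq_along(spec$layers)) {
    l <- spec$layers[[i]]
    if (l$kind == "conv1d") {
      len <- as.integer(floor((len - l$kernel) / l$stride) + 1)
      ch <- as.integer(l$filters)
    } else if (l$kind == "maxpool1d") {
      len <- as.integer(floor((len - l$pool) / l$stride) + 1)
    } else if (l$kind == "lstm") {
      len <- 1L
      ch <- as.integer(l$units)
    } else if (l$kind == "flatten") {
      ch <- as.integer(len * ch)
      len <- 1L
    } else if (l$kind == "dense") {
      len <- 1L
      ch <- as.integer(l$units)
    }
    if (len < 1) {
      abort(sprintf("layer %d (%s) produces non-positive length %d", i, l$kind, len),
            "seizr_shape_error")
    }
    rows[[i]] <- data.frame(layer = i, kind = l$kind, out_len = len,
                            out_ch = ch)
  }
  do.call(rbind, rows)
}

#' Analytic parameter counts
#'
#' Conventions (matching the usual deep-learning bookkeeping): a convolution
#' has `filters * kernel * in_channels + filters` parameters; batch norm has
#' `4 * channels` (scale, offset, and the two moving statistics); an LSTM has
#' `4 * ((in_features + units) * units + units)`; a dense layer has
#' `in * units + units`; everything else has none.
#'
#' @param spec a [model_spec].
#' @return list with `per_layer` (integer vector) and `total`.
#' @export
count_parameters <- function(spec) {
  shapes <- infer_shapes(spec)
  len <- spec$input_length
  ch <- spec$input_channels
  per_layer <- numeric(length(spec$layers))
  for (i in seq_along(spec$layers)) {
    l <- spec$layers[[i]]
    per_layer[i] <- switch(l$kind,
      conv1d = l$filters * (l$kernel * ch) + l$filters,
      batchnorm = 4 * ch,
      lstm = 4 * ((ch + l$units) * l$units + l$units),
      dense = ch * l$units + l$units,
      0
    )
    ch <- shapes$out_ch[i]
    len <- shapes$out_len[i]
  }
  list(per_layer = per_layer, total = sum(per_layer))
}

#' Print a Table-style model summary
#'
#' @param spec a [model_spec].
#' @return invisibly, a data frame with layer kind, output shape and
#'   parameter count (also printed).
#' @export
describe_model <- function(spec) {
  shapes <- infer_shapes(spec)
  params <- count_parameters(spec)
  df <- data.frame(
    layer = shapes$layer, kind = shapes$kind,
    output_shape = sprintf("(%d,%d)", shapes$out_len, shapes$out_ch),
    parameters = params$per_layer
  )
  print(df, row.names = FALSE)
  cat(sprintf("Total parameters: %s\n",
              format(params$total, big.mark = ",")))
  invisible(df)
}

#' Serialize / deserialize a model spec as JSON
#'
#' @param spec a [model_spec].
#' @param path file path.
#' @return `spec_to_json` invisibly returns `path`; `spec_from_json` returns
#'   the reconstructed [model_spec].
#' @export
spec_to_json <- function(spec, path) {
  x <- list(input_length = spec$input_length, n_classes = spec$n_classes,
            layers = lapply(spec$layers, function(l) Filter(Negate(is.null), l)))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname spec_to_json
#' @export
spec_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  layers <- lapply(x$layers, function(l) {
    do.call(layer_spec, l[setdiff(names(l), "padding")])
  })
  model_spec(x$input_length, layers, x$n_classes)
}
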