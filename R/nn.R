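## The network engine. Activations for a batch of B sequences of length L
## with C channels are stored as a (B*L) x C matrix whose row b + B*(t-1)
## holds timestep t of sample b; convolution and pooling then reduce to
## gather -> matrix-multiply -> scatter, which keeps everything in BLAS
## calls. Backward passes are exact gradients (checked against numerical
## differentiation in the test suite).

.rep_row <- function(v, n) matrix(v, n, length(v), byrow = TRUE)

# Row indices of tap j (1-based) for every output position, all samples.
.win_rows <- function(B, L_out, stride, j) {
  as.vector(outer(seq_len(B), ((seq_len(L_out) - 1L) * stride + (j - 1L)) * B, "+"))
}

.glorot <- function(nr, nc, fan_in = nr, fan_out = nc) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' Materialize a trainable network from a model spec
#'
#' Allocates every weight array of the architecture (Glorot-uniform
#' initialized under the given seed; LSTM forget-gate biases start at 1) plus
#' the batch-norm moving statistics. The materialized arrays are what
#' [model_parameter_count] counts, giving an implementation-level cross-check
#' of the analytic [count_parameters] oracle.
#'
#' @param spec a [model_spec].
#' @param seed integer seed for weight initialization.
#' @param init `"glorot"` (default) or `"zeros"` (all weights zero; useful
#'   for degenerate-case checks).
#' @return an object of class `seizr_model`.
#' @export
build <- function(spec, seed = 1L, init = c("glorot", "zeros")) {
  assert(inherits(spec, "model_spec"), "spec must be a model_spec")
  init <- match.arg(init)
  shapes <- infer_shapes(spec)  # errors name the failing layer
  with_seed(seed, {
    L <- spec$input_length
    C <- spec$input_channels
    layers <- vector("list", length(spec$layers))
    for (i in seq_along(spec$layers)) {
      l <- spec$layers[[i]]
      lay <- list(kind = l$kind, cfg = l, in_len = L, in_ch = C,
                  params = list(), state = list())
      if (l$kind == "conv1d") {
        W <- if (init == "zeros") matrix(0, l$kernel * C, l$filters) else
          .glorot(l$kernel * C, l$filters,
                  fan_in = l$kernel * C, fan_out = l$kernel * l$filters)
        lay$params <- list(W = W, b = numeric(l$filters))
      } else if (l$kind == "batchnorm") {
        lay$params <- list(gamma = rep(1, C), beta = numeric(C))
        lay$state <- list(mean = numeric(C), var = rep(1, C), momentum = 0.9,
                          eps = 1e-5)
      } else if (l$kind == "lstm") {
        U <- l$units
        mk <- function(nr, nc) if (init == "zeros") matrix(0, nr, nc) else
          .glorot(nr, nc)
        b <- numeric(4 * U)
        b[(U + 1):(2 * U)] <- 1  # forget-gate bias
        lay$params <- list(Wx = mk(C, 4 * U), Wh = mk(U, 4 * U), b = b)
      } else if (l$kind == "dense") {
        W <- if (init == "zeros") matrix(0, C, l$units) else .glorot(C, l$units)
        lay$params <- list(W = W, b = numeric(l$units))
      }
      L <- shapes$out_len[i]
      C <- shapes$out_ch[i]
      lay$out_len <- L
      lay$out_ch <- C
      layers[[i]] <- lay
    }
    structure(list(spec = spec, layers = layers), class = "seizr_model")
  })
}

#' @export
print.seizr_model <- function(x, ...) {
  cat(sprintf("<seizr_model: input (%d,1), %d layers, %s parameters, %s head>\n",
              x$spec$input_length, length(x$layers),
              format(model_parameter_count(x), big.mark = ","), x$spec$head))
  invisible(x)
}

#' Count the parameters actually materialized in a built model
#'
#' Sums the lengths of every weight array plus the batch-norm moving
#' statistics (the same convention the analytic counter uses).
#'
#' @param model a built `seizr_model`.
#' @return integer total.
#' @export
model_parameter_count <- function(model) {
  tot <- 0
  for (lay in model$layers) {
    tot <- tot + sum(vapply(lay$params, length, numeric(1)))
    if (lay$kind == "batchnorm") {
      tot <- tot + length(lay$state$mean) + length(lay$state$var)
    }
  }
  as.integer(tot)
}

## ---- per-layer forward/backward -------------------------------------------

.fwd_conv <- function(lay, x, B, training) {
  l <- lay$cfg
  L_out <- lay$out_len
  k <- l$kernel
  C <- lay$in_ch
  P <- matrix(0, B * L_out, k * C)
  rows <- vector("list", k)
  for (j in seq_len(k)) {
    rows[[j]] <- .win_rows(B, L_out, l$stride, j)
    P[, ((j - 1L) * C + 1L):(j * C)] <- x[rows[[j]], , drop = FALSE]
  }
  y <- P %*% lay$params$W
  y <- y + .rep_row(lay$params$b, nrow(y))
  list(out = y, cache = list(P = P, rows = rows, in_rows = nrow(x)))
}

.bwd_conv <- function(lay, cache, dy) {
  l <- lay$cfg
  C <- lay$in_ch
  dW <- crossprod(cache$P, dy)
  db <- colSums(dy)
  dP <- tcrossprod(dy, lay$params$W)
  dx <- matrix(0, cache$in_rows, C)
  for (j in seq_along(cache$rows)) {
    idx <- cache$rows[[j]]
    dx[idx, ] <- dx[idx, ] + dP[, ((j - 1L) * C + 1L):(j * C), drop = FALSE]
  }
  list(dx = dx, grads = list(W = dW, b = db))
}

.fwd_pool <- function(lay, x, B, training) {
  l <- lay$cfg
  L_out <- lay$out_len
  rows <- vector("list", l$pool)
  rows[[1]] <- .win_rows(B, L_out, l$stride, 1L)
  y <- x[rows[[1]], , drop = FALSE]
  amax <- matrix(1L, nrow(y), ncol(y))
  for (j in 2:l$pool) {
    rows[[j]] <- .win_rows(B, L_out, l$stride, j)
    cand <- x[rows[[j]], , drop = FALSE]
    upd <- cand > y
    y[upd] <- cand[upd]
    amax[upd] <- j
  }
  list(out = y, cache = list(rows = rows, amax = amax, in_rows = nrow(x)))
}

.bwd_pool <- function(lay, cache, dy) {
  dx <- matrix(0, cache$in_rows, ncol(dy))
  for (j in seq_along(cache$rows)) {
    contrib <- dy * (cache$amax == j)
    idx <- cache$rows[[j]]
    dx[idx, ] <- dx[idx, ] + contrib
  }
  list(dx = dx, grads = list())
}

.fwd_bn <- function(lay, x, B, training) {
  st <- lay$state
  N <- nrow(x)
  if (training) {
    m <- colMeans(x)
    xc <- x - .rep_row(m, N)
    v <- colMeans(xc^2)
  } else {
    m <- st$mean
    v <- st$var
    xc <- x - .rep_row(m, N)
  }
  invstd <- 1 / sqrt(v + st$eps)
  xhat <- xc * .rep_row(invstd, N)
  y <- xhat * .rep_row(lay$params$gamma, N) + .rep_row(lay$params$beta, N)
  list(out = y,
       cache = list(xhat = xhat, invstd = invstd, N = N, batch_mean = m,
                    batch_var = v, training = training))
}

.bwd_bn <- function(lay, cache, dy) {
  N <- cache$N
  xhat <- cache$xhat
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  dxhat <- dy * .rep_row(lay$params$gamma, N)
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * xhat)
  dx <- (dxhat - .rep_row(s1 / N, N) - xhat * .rep_row(s2 / N, N)) *
    .rep_row(cache$invstd, N)
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

.fwd_relu <- function(lay, x, B, training) {
  mask <- x > 0
  list(out = x * mask, cache = list(mask = mask))
}

.fwd_dropout <- function(lay, x, B, training) {
  if (!training || lay$cfg$rate <= 0) {
    return(list(out = x, cache = list(mask = NULL)))
  }
  keep <- 1 - lay$cfg$rate
  mask <- matrix((stats::runif(length(x)) < keep) / keep, nrow(x), ncol(x))
  list(out = x * mask, cache = list(mask = mask))
}

.fwd_flatten <- function(lay, x, B, training) {
  L <- lay$in_len
  C <- lay$in_ch
  if (L == 1L) return(list(out = x, cache = list(identity = TRUE)))
  y <- matrix(0, B, L * C)
  for (t in seq_len(L)) {
    y[, ((t - 1L) * C + 1L):(t * C)] <- x[((t - 1L) * B + 1L):(t * B), , drop = FALSE]
  }
  list(out = y, cache = list(identity = FALSE))
}

.bwd_flatten <- function(lay, cache, dy) {
  if (cache$identity) return(list(dx = dy, grads = list()))
  L <- lay$in_len
  C <- lay$in_ch
  B <- nrow(dy)
  dx <- matrix(0, B * L, C)
  for (t in seq_len(L)) {
    dx[((t - 1L) * B + 1L):(t * B), ] <- dy[, ((t - 1L) * C + 1L):(t * C), drop = FALSE]
  }
  list(dx = dx, grads = list())
}

.sigm <- function(z) 1 / (1 + exp(-z))

.fwd_lstm <- function(lay, x, B, training) {
  U <- lay$cfg$units
  Tn <- lay$in_len
  h <- matrix(0, B, U)
  cc <- matrix(0, B, U)
  steps <- vector("list", Tn)
  Wx <- lay$params$Wx
  Wh <- lay$params$Wh
  b <- lay$params$b
  for (t in seq_len(Tn)) {
    xt <- x[((t - 1L) * B + 1L):(t * B), , drop = FALSE]
    z <- xt %*% Wx + h %*% Wh + .rep_row(b, B)
    i <- .sigm(z[, 1:U, drop = FALSE])
    f <- .sigm(z[, (U + 1):(2 * U), drop = FALSE])
    g <- tanh(z[, (2 * U + 1):(3 * U), drop = FALSE])
    o <- .sigm(z[, (3 * U + 1):(4 * U), drop = FALSE])
    c_prev <- cc
    cc <- f * cc + i * g
    h <- o * tanh(cc)
    steps[[t]] <- list(xt = xt, h_prev = if (t == 1L) matrix(0, B, U) else
      steps[[t - 1L]]$h, c_prev = c_prev, i = i, f = f, g = g, o = o, c = cc,
      h = h)
  }
  list(out = h, cache = list(steps = steps, B = B, Tn = Tn))
}

.bwd_lstm <- function(lay, cache, dy) {
  U <- lay$cfg$units
  B <- cache$B
  Tn <- cache$Tn
  Wx <- lay$params$Wx
  Wh <- lay$params$Wh
  dWx <- matrix(0, nrow(Wx), ncol(Wx))
  dWh <- matrix(0, nrow(Wh), ncol(Wh))
  db <- numeric(4 * U)
  dx <- matrix(0, B * Tn, lay$in_ch)
  dh <- dy
  dc <- matrix(0, B, U)
  for (t in rev(seq_len(Tn))) {
    s <- cache$steps[[t]]
    tc <- tanh(s$c)
    do <- dh * tc * s$o * (1 - s$o)
    dc <- dc + dh * s$o * (1 - tc^2)
    di <- dc * s$g * s$i * (1 - s$i)
    dg <- dc * s$i * (1 - s$g^2)
    df <- dc * s$c_prev * s$f * (1 - s$f)
    dc <- dc * s$f
    dz <- cbind(di, df, dg, do)
    dWx <- dWx + crossprod(s$xt, dz)
    dWh <- dWh + crossprod(s$h_prev, dz)
    db <- db + colSums(dz)
    dx[((t - 1L) * B + 1L):(t * B), ] <- dz %*% t(Wx)
    dh <- dz %*% t(Wh)
  }
  list(dx = dx, grads = list(Wx = dWx, Wh = dWh, b = db))
}

.fwd_dense <- function(lay, x, B, training) {
  z <- x %*% lay$params$W + .rep_row(lay$params$b, nrow(x))
  act <- lay$cfg$activation
  if (!is.null(act) && act == "relu") {
    mask <- z > 0
    list(out = z * mask, cache = list(x = x, mask = mask))
  } else {
    list(out = z, cache = list(x = x, mask = NULL))
  }
}

.bwd_dense <- function(lay, cache, dy) {
  dz <- if (is.null(cache$mask)) dy else dy * cache$mask
  dW <- crossprod(cache$x, dz)
  if (lay$cfg$l2 > 0) dW <- dW + 2 * lay$cfg$l2 * lay$params$W
  list(dx = tcrossprod(dz, lay$params$W),
       grads = list(W = dW, b = colSums(dz)))
}

## ---- whole-network passes -------------------------------------------------

# x_feat: n x input_length matrix. Returns logits plus per-layer caches and
# realized output shapes (len, ch).
nn_forward <- function(model, x_feat, training = FALSE) {
  B <- nrow(x_feat)
  x <- matrix(as.vector(x_feat), ncol = 1L)  # row b + B*(t-1) = sample b, time t
  caches <- vector("list", length(model$layers))
  shapes <- matrix(0L, length(model$layers), 2L)
  for (i in seq_along(model$layers)) {
    lay <- model$layers[[i]]
    r <- switch(lay$kind,
      conv1d = .fwd_conv(lay, x, B, training),
      maxpool1d = .fwd_pool(lay, x, B, training),
      batchnorm = .fwd_bn(lay, x, B, training),
      relu = .fwd_relu(lay, x, B, training),
      dropout = .fwd_dropout(lay, x, B, training),
      flatten = .fwd_flatten(lay, x, B, training),
      lstm = .fwd_lstm(lay, x, B, training),
      dense = .fwd_dense(lay, x, B, training),
      activation = list(out = x, cache = list())
    )
    if (is.null(r)) {
      abort(sprintf("layer %d (%s) failed to construct", i, lay$kind),
            "seizr_construction_error")
    }
    x <- r$out
    caches[[i]] <- r$cache
    shapes[i, ] <- c(nrow(x) / B, ncol(x))
  }
  list(logits = x, caches = caches, shapes = shapes, B = B)
}

# Backward from d(logits); returns list of gradient lists parallel to layers.
nn_backward <- function(model, fwd, dlogits) {
  grads <- vector("list", length(model$layers))
  dy <- dlogits
  for (i in rev(seq_along(model$layers))) {
    lay <- model$layers[[i]]
    cache <- fwd$caches[[i]]
    r <- switch(lay$kind,
      conv1d = .bwd_conv(lay, cache, dy),
      maxpool1d = .bwd_pool(lay, cache, dy),
      batchnorm = .bwd_bn(lay, cache, dy),
      relu = list(dx = dy * cache$mask, grads = list()),
      dropout = if (is.null(cache$mask)) list(dx = dy, grads = list()) else
        list(dx = dy * cache$mask, grads = list()),
      flatten = .bwd_flatten(lay, cache, dy),
      lstm = .bwd_lstm(lay, cache, dy),
      dense = .bwd_dense(lay, cache, dy),
      activation = list(dx = dy, grads = list())
    )
    grads[[i]] <- r$grads
    dy <- r$dx
  }
  grads
}

# Update batch-norm running statistics from the caches of a training pass.
.update_bn_state <- function(model, fwd) {
  for (i in seq_along(model$layers)) {
    if (model$layers[[i]]$kind == "batchnorm") {
      st <- model$layers[[i]]$state
      cc <- fwd$caches[[i]]
      mom <- st$momentum
      model$layers[[i]]$state$mean <- mom * st$mean + (1 - mom) * cc$batch_mean
      model$layers[[i]]$state$var <- mom * st$var + (1 - mom) * cc$batch_var
    }
  }
  model
}

# Head probabilities from logits.
.head_probs <- function(model, logits) {
  if (model$spec$head == "sigmoid") {
    .sigm(logits)
  } else {
    z <- logits - apply(logits, 1, max)
    e <- exp(z)
    e / rowSums(e)
  }
}

# Loss (weighted mean NLL + L2 penalties) and gradient w.r.t. logits.
.head_loss <- function(model, logits, y, class_weights) {
  B <- nrow(logits)
  w <- if (is.null(class_weights)) rep(1, B) else class_weights[y + 1L]
  p <- .head_probs(model, logits)
  eps <- 1e-12
  if (model$spec$head == "sigmoid") {
    pc <- pmin(pmax(p[, 1L], eps), 1 - eps)
    nll <- -(y * log(pc) + (1 - y) * log(1 - pc))
    dlogits <- matrix(w * (p[, 1L] - y) / B, ncol = 1L)
  } else {
    K <- ncol(p)
    Y <- matrix(0, B, K)
    Y[cbind(seq_len(B), y + 1L)] <- 1
    pc <- pmax(p[cbind(seq_len(B), y + 1L)], eps)
    nll <- -log(pc)
    dlogits <- (p - Y) * (w / B)
  }
  l2 <- 0
  for (lay in model$layers) {
    if (lay$kind == "dense" && lay$cfg$l2 > 0) {
      l2 <- l2 + lay$cfg$l2 * sum(lay$params$W^2)
    }
  }
  list(loss = mean(w * nll) + l2, dlogits = dlogits, probs = p)
}

## ---- optimization ----------------------------------------------------------

.adam_init <- function(model) {
  lapply(model$layers, function(lay) {
    lapply(lay$params, function(p) list(m = p * 0, v = p * 0))
  })
}

.adam_step <- function(model, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (i in seq_along(model$layers)) {
    for (nm in names(grads[[i]])) {
      g <- grads[[i]][[nm]]
      s <- state[[i]][[nm]]
      s$m <- beta1 * s$m + (1 - beta1) * g
      s$v <- beta2 * s$v + (1 - beta2) * g^2
      state[[i]][[nm]] <- s
      model$layers[[i]]$params[[nm]] <- model$layers[[i]]$params[[nm]] -
        lr * (s$m / bc1) / (sqrt(s$v / bc2) + eps)
    }
  }
  list(model = model, state = state)
}

## ---- user-facing training / prediction ------------------------------------

#' Train a built model
#'
#' Mini-batch Adam on (binary or categorical) cross-entropy, with optional
#' per-class loss weights and reshuffling of the training order before
#' training and at the end of every epoch.
#'
#' @param model a built `seizr_model`.
#' @param x n x input_length feature matrix.
#' @param y integer class labels in `[0, n_classes)`.
#' @param epochs number of passes over the data.
#' @param lr Adam learning rate.
#' @param batch_size mini-batch size.
#' @param class_weights numeric vector of per-class loss weights (index
#'   `c + 1` weighs class id `c`), or `NULL` for unweighted loss.
#' @param x_val,y_val optional validation data monitored per epoch.
#' @param seed integer seed driving shuffling and dropout.
#' @param verbose print one line per epoch.
#' @return list with the trained `model` and a `history` data frame
#'   (`epoch`, `loss`, `acc`, `val_loss`, `val_acc`).
#' @export
fit_model <- function(model, x, y, epochs = 10L, lr = 1e-4, batch_size = 60L,
                      class_weights = NULL, x_val = NULL, y_val = NULL,
                      seed = 1L, verbose = FALSE) {
  assert(inherits(model, "seizr_model"), "model must be a built seizr_model")
  assert(nrow(x) == length(y), "x rows must match length(y)")
  n <- nrow(x)
  opt <- .adam_init(model)
  step <- 0L
  hist <- data.frame(epoch = integer(), loss = numeric(), acc = numeric(),
                     val_loss = numeric(), val_acc = numeric())
  with_seed(seed, {
    order <- sample.int(n)
    for (ep in seq_len(epochs)) {
      ep_loss <- 0
      ep_hits <- 0
      nb <- 0L
      for (start in seq(1L, n, by = batch_size)) {
        idx <- order[start:min(start + batch_size - 1L, n)]
        xb <- x[idx, , drop = FALSE]
        yb <- y[idx]
        fwd <- nn_forward(model, xb, training = TRUE)
        hl <- .head_loss(model, fwd$logits, yb, class_weights)
        grads <- nn_backward(model, fwd, hl$dlogits)
        model <- .update_bn_state(model, fwd)
        step <- step + 1L
        upd <- .adam_step(model, grads, opt, lr, step)
        model <- upd$model
        opt <- upd$state
        ep_loss <- ep_loss + hl$loss * length(idx)
        ep_hits <- ep_hits + sum(.probs_to_class(model, hl$probs) == yb)
        nb <- nb + length(idx)
      }
      val_loss <- NA_real_
      val_acc <- NA_real_
      if (!is.null(x_val) && nrow(x_val) > 0) {
        fv <- nn_forward(model, x_val, training = FALSE)
        hv <- .head_loss(model, fv$logits, y_val, class_weights)
        val_loss <- hv$loss
        val_acc <- mean(.probs_to_class(model, hv$probs) == y_val)
      }
      hist <- rbind(hist, data.frame(
        epoch = ep, loss = ep_loss / nb, acc = ep_hits / nb,
        val_loss = val_loss, val_acc = val_acc))
      if (verbose) {
        message(sprintf("epoch %3d  loss %.4f  acc %.3f  val_acc %.3f",
                        ep, ep_loss / nb, ep_hits / nb, val_acc))
      }
      order <- sample.int(n)  # reshuffle for the next epoch
    }
  })
  list(model = model, history = hist)
}

.probs_to_class <- function(model, probs, threshold = 0.5) {
  if (model$spec$head == "sigmoid") {
    as.integer(probs[, 1L] >= threshold)
  } else {
    max.col(probs) - 1L
  }
}

#' Predict class probabilities
#'
#' @param object a trained `seizr_model`.
#' @param x n x input_length feature matrix.
#' @param batch_size forward-pass batch size.
#' @param ... unused.
#' @return an n x 1 (sigmoid) or n x K (softmax) probability matrix.
#' @export
predict.seizr_model <- function(object, x, batch_size = 256L, ...) {
  n <- nrow(x)
  out <- NULL
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    fwd <- nn_forward(object, x[idx, , drop = FALSE], training = FALSE)
    p <- .head_probs(object, fwd$logits)
    out <- rbind(out, p)
  }
  out
}

#' Hard class predictions
#'
#' @param model a trained `seizr_model`.
#' @param x feature matrix.
#' @param threshold sigmoid decision threshold (default 0.5).
#' @return integer class ids.
#' @export
predict_classes <- function(model, x, threshold = 0.5) {
  .probs_to_class(model, predict(model, x), threshold)
}
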