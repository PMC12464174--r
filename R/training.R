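#' Training configuration
#'
#' Defaults follow the reference training regime: Adam with learning rate
#' 1e-4, batch size 60, 300 epochs, 10 folds, a 0.15 validation split carved
#' out of each fold's training portion (i.e. 76.5% train / 13.5% validation /
#' 10% test per fold), inverse-frequency class weighting, and reshuffling
#' before training and after every epoch. Desk-scale runs should lower
#' `epochs` (and may raise `lr`); see the package vignette.
#'
#' @param k_folds number of cross-validation folds.
#' @param val_split fraction of the training portion held out for validation.
#' @param lr Adam learning rate.
#' @param batch_size mini-batch size.
#' @param epochs training epochs per fold.
#' @param class_weighting `"inverse_frequency"` or `"none"`.
#' @param seed master seed for folds, shuffling, initialization and dropout.
#' @return a `train_config` list.
#' @export
train_config <- function(k_folds = 10L, val_split = 0.15, lr = 1e-4,
                         batch_size = 60L, epochs = 300L,
                         class_weighting = c("inverse_frequency", "none"),
                         seed = 1L) {
  assert(is_count(k_folds) && k_folds >= 2, "k_folds must be >= 2")
  assert(val_split > 0 && val_split < 1, "val_split must lie in (0, 1)")
  class_weighting <- match.arg(class_weighting)
  structure(list(k_folds = as.integer(k_folds), val_split = val_split,
                 lr = lr, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 class_weighting = class_weighting, seed = as.integer(seed)),
            class = "train_config")
}

#' Stratified k-fold assignment
#'
#' Shuffles each class separately under the seed and deals its members
#' round-robin across folds, so every fold's class proportions are within
#' one sample of the global proportions and the folds partition the index
#' set.
#'
#' @param labels integer class labels.
#' @param k number of folds (every class must have at least `k` members).
#' @param seed integer seed.
#' @return list of `k` integer index vectors (1-based, disjoint, covering
#'   `seq_along(labels)`).
#' @export
stratified_folds <- function(labels, k, seed = 1L) {
  assert(is_count(k) && k >= 2, "k must be >= 2")
  classes <- sort(unique(labels))
  sizes <- vapply(classes, function(cl) sum(labels == cl), numeric(1))
  if (any(sizes < k)) {
    abort(sprintf("class %s has fewer than k = %d members",
                  classes[which(sizes < k)[1]], k), "seizr_stratification_error")
  }
  folds <- vector("list", k)
  with_seed(seed, {
    offset <- 0L
    for (cl in classes) {
      idx <- sample(which(labels == cl))
      for (j in seq_along(idx)) {
        f <- ((j - 1L + offset) %% k) + 1L
        folds[[f]] <- c(folds[[f]], idx[j])
      }
      # stagger the round-robin start so remainders spread across folds
      offset <- (offset + length(idx)) %% k
    }
  })
  folds
}

#' Inverse-frequency class weights
#'
#' `weight_c = n_total / (n_classes * n_c)`: each class contributes the same
#' total weight to the loss, and balanced classes get weight 1.
#'
#' @param labels integer class labels (every class present must be
#'   non-empty; classes are `0 .. max(labels)`).
#' @return numeric vector of weights, entry `c + 1` weighing class `c`.
#' @export
class_weights <- function(labels) {
  k <- max(labels) + 1L
  counts <- vapply(0:(k - 1L), function(cl) sum(labels == cl), numeric(1))
  assert(all(counts > 0), "every class must have at least one sample",
         class = "seizr_empty_class")
  length(labels) / (k * counts)
}

# Stratified validation split of a training index set: returns
# list(train, val) with ~val_split of each class moved to val.
.val_split <- function(idx, labels, val_split, seed) {
  with_seed(seed, {
    val <- integer(0)
    for (cl in unique(labels[idx])) {
      cl_idx <- idx[labels[idx] == cl]
      n_val <- max(1L, round(val_split * length(cl_idx)))
      val <- c(val, sample(cl_idx, n_val))
    }
    list(train = setdiff(idx, val), val = val)
  })
}

#' Class-weighted stratified k-fold cross-validation of the CNN-LSTM
#'
#' For each fold: the fold is the test set; a stratified `val_split` share of
#' the remaining data becomes the validation set (so with 10 folds and a
#' 0.15 split the data divides 76.5/13.5/10); a model is built fresh from
#' `spec_fn`, trained with per-epoch reshuffling and (optionally)
#' inverse-frequency class weights, and evaluated on the held-out fold.
#' Feature extraction is stateless per window, so nothing is fitted outside
#' the training loop and no fold leakage can occur.
#'
#' @param features list with `x` (n x p matrix) and `y` (labels), e.g. from
#'   [featurize_dataset].
#' @param cfg a [train_config].
#' @param spec_fn function `(input_length, n_classes) -> model_spec`
#'   (default [default_spec]); swap in [ablated_spec] constructions here.
#' @param n_classes number of classes (default inferred from labels).
#' @param verbose print fold progress.
#' @return object of class `cv_result`: list with `folds` (per-fold lists:
#'   `fold`, `test_idx`, `history`, `report`, `accuracy`, `probs`),
#'   `accuracies`, `aggregate` (mean and sd of the seven metrics over folds)
#'   and `config`.
#' @export
run_cv <- function(features, cfg = train_config(), spec_fn = default_spec,
                   n_classes = NULL, verbose = FALSE) {
  x <- features$x
  y <- features$y
  if (is.null(n_classes)) n_classes <- max(y) + 1L
  folds <- stratified_folds(y, cfg$k_folds, cfg$seed)
  cw <- if (cfg$class_weighting == "inverse_frequency") class_weights(y) else NULL
  spec <- spec_fn(ncol(x), n_classes)
  fold_out <- vector("list", length(folds))
  for (f in seq_along(folds)) {
    test_idx <- folds[[f]]
    rest <- setdiff(seq_along(y), test_idx)
    sp <- .val_split(rest, y, cfg$val_split, derive_seed(cfg$seed, 1000 + f))
    model <- build(spec, seed = derive_seed(cfg$seed, f))
    fit <- fit_model(model, x[sp$train, , drop = FALSE], y[sp$train],
                     epochs = cfg$epochs, lr = cfg$lr,
                     batch_size = cfg$batch_size, class_weights = cw,
                     x_val = x[sp$val, , drop = FALSE], y_val = y[sp$val],
                     seed = derive_seed(cfg$seed, 2000 + f))
    probs <- predict(fit$model, x[test_idx, , drop = FALSE])
    pred <- .probs_to_class(fit$model, probs)
    report <- evaluate_predictions(y[test_idx], pred, n_classes)
    fold_out[[f]] <- list(fold = f, test_idx = test_idx,
                          train_idx = sp$train, val_idx = sp$val,
                          history = fit$history, report = report,
                          accuracy = mean(pred == y[test_idx]) * 100,
                          probs = probs)
    if (verbose) {
      message(sprintf("fold %d/%d: test accuracy %.2f%%", f, length(folds),
                      fold_out[[f]]$accuracy))
    }
  }
  .cv_result(fold_out, cfg)
}

.cv_result <- function(fold_out, cfg) {
  metric_mat <- do.call(rbind, lapply(fold_out, function(fr) fr$report$metrics))
  structure(list(
    folds = fold_out,
    accuracies = vapply(fold_out, function(fr) fr$accuracy, numeric(1)),
    aggregate = list(mean = colMeans(metric_mat, na.rm = TRUE),
                     sd = apply(metric_mat, 2, stats::sd, na.rm = TRUE)),
    config = cfg
  ), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result: %d folds>\n", length(x$folds)))
  agg <- sprintf("%s = %.2f +/- %.2f", names(x$aggregate$mean),
                 x$aggregate$mean, x$aggregate$sd)
  cat(" ", paste(agg, collapse = "\n  "), "\n")
  invisible(x)
}
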