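#' Classical machine-learning baselines on the shared folds
#'
#' Runs one of the five reference classifiers — support vector classifier,
#' k-nearest neighbours, Gaussian naive Bayes, decision tree, multi-layer
#' perceptron — over the same stratified folds (same seed scheme) as
#' [run_cv], so fold-wise accuracies are paired and [compare_models] is
#' valid. Hyperparameters are the library defaults, frozen here:
#' radial-kernel SVC (`e1071::svm`), `k = 5` KNN (`class::knn`),
#' `e1071::naiveBayes`, `rpart` with default complexity, and a 16-unit
#' single-hidden-layer `nnet` with weight decay 1e-4. Constant features
#' (zero training-set variance) are dropped before fitting, since several of
#' these models cannot digest them.
#'
#' @param name one of `"SVC"`, `"KNN"`, `"GNB"`, `"DT"`, `"MLP"`.
#' @param features list with `x` and `y` (same object passed to [run_cv]).
#' @param cfg a [train_config] (only `k_folds` and `seed` are used).
#' @return a `cv_result` with per-fold metric reports and accuracies.
#' @export
run_baseline <- function(name, features, cfg = train_config()) {
  if (!name %in% c("SVC", "KNN", "GNB", "DT", "MLP")) {
    abort(sprintf("unknown baseline '%s'", name), "seizr_config_error")
  }
  x <- features$x
  y <- features$y
  n_classes <- max(y) + 1L
  folds <- stratified_folds(y, cfg$k_folds, cfg$seed)
  fold_out <- vector("list", length(folds))
  for (f in seq_along(folds)) {
    test_idx <- folds[[f]]
    train_idx <- setdiff(seq_along(y), test_idx)
    xtr <- x[train_idx, , drop = FALSE]
    keep <- apply(xtr, 2, stats::sd) > 0
    if (!any(keep)) keep[1] <- TRUE
    xtr <- xtr[, keep, drop = FALSE]
    xte <- x[test_idx, keep, drop = FALSE]
    ytr <- factor(y[train_idx], levels = 0:(n_classes - 1L))
    pred <- with_seed(derive_seed(cfg$seed, 3000 + f), {
      .fit_predict_baseline(name, xtr, ytr, xte)
    })
    pred <- as.integer(as.character(pred))
    report <- evaluate_predictions(y[test_idx], pred, n_classes)
    fold_out[[f]] <- list(fold = f, test_idx = test_idx, report = report,
                          accuracy = mean(pred == y[test_idx]) * 100,
                          history = NULL, probs = NULL)
  }
  .cv_result(fold_out, cfg)
}

.fit_predict_baseline <- function(name, xtr, ytr, xte) {
  switch(name,
    SVC = {
      fit <- e1071::svm(xtr, ytr, type = "C-classification", scale = FALSE)
      stats::predict(fit, xte)
    },
    KNN = class::knn(xtr, xte, ytr, k = 5L),
    GNB = {
      fit <- e1071::naiveBayes(xtr, ytr)
      stats::predict(fit, xte)
    },
    DT = {
      df_tr <- data.frame(xtr)
      df_tr$.y <- ytr
      fit <- rpart::rpart(.y ~ ., data = df_tr, method = "class")
      df_te <- data.frame(xte)
      names(df_te) <- names(df_tr)[seq_len(ncol(xte))]
      stats::predict(fit, df_te, type = "class")
    },
    MLP = {
      fit <- nnet::nnet(xtr, stats::model.matrix(~ ytr - 1), size = 16L,
                        decay = 1e-4, maxit = 200L, trace = FALSE,
                        MaxNWts = 1e6, softmax = TRUE)
      cls <- stats::predict(fit, xte, type = "class")
      factor(sub("^ytr", "", cls), levels = levels(ytr))
    }
  )
}

#' Architecture ablations of the default CNN-LSTM
#'
#' Minimal-surgery variants used to probe which stage carries the
#' performance:
#' \describe{
#'   \item{`no_dwt`}{the unchanged default architecture, but meant to be fed
#'     the raw z-scored window flattened channel-major (pass the raw
#'     flattened length as `input_length`).}
#'   \item{`no_lstm`}{the LSTM is removed; the final convolutional feature
#'     map is flattened straight into the dense head.}
#'   \item{`no_cnn`}{the convolutional stack is removed; the wavelet vector,
#'     viewed as a `(length, 1)` sequence, feeds the 200-unit LSTM directly,
#'     then the dense head.}
#' }
#'
#' @param which one of `"no_dwt"`, `"no_lstm"`, `"no_cnn"`.
#' @param input_length length of the 1D input the variant consumes.
#' @param n_classes number of classes.
#' @return a [model_spec].
#' @export
ablated_spec <- function(which = c("no_dwt", "no_lstm", "no_cnn"),
                         input_length, n_classes = 2L) {
  which <- match.arg(which)
  if (which == "no_dwt") {
    return(default_spec(input_length, n_classes))
  }
  full <- default_spec(input_length, n_classes)
  kinds <- vapply(full$layers, function(l) l$kind, "")
  if (which == "no_lstm") {
    layers <- full$layers[kinds != "lstm"]
  } else {
    first_keep <- base::which(kinds == "lstm")[1]
    layers <- full$layers[seq(first_keep, length(full$layers))]
  }
  model_spec(input_length, layers, n_classes)
}
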