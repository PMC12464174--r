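#' Binary confusion matrix from labels and predictions
#'
#' @param y_true,y_pred integer vectors of 0/1 labels (1 = positive/seizure).
#' @return list with counts `TP`, `FN`, `TN`, `FP` of class
#'   `confusion_matrix`.
#' @export
confusion_counts <- function(y_true, y_pred) {
  assert(length(y_true) == length(y_pred), "length mismatch")
  structure(list(
    TP = sum(y_true == 1 & y_pred == 1),
    FN = sum(y_true == 1 & y_pred == 0),
    TN = sum(y_true == 0 & y_pred == 0),
    FP = sum(y_true == 0 & y_pred == 1)
  ), class = "confusion_matrix")
}

#' The seven confusion-matrix metrics, percent scale
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, accuracy
#' `(TP+TN)/total`, positive and negative predictive value, the Matthews
#' correlation coefficient
#' `(TP*TN - FN*FP) / sqrt((TP+FN)(TP+FP)(TN+FN)(TN+FP))` and F1
#' `2TP/(2TP+FN+FP)` — all multiplied by 100. A ratio with a zero
#' denominator is reported as `NA` and flagged in `undefined`, never
#' silently coerced to 0.
#'
#' @param cm a `confusion_matrix` (from [confusion_counts]) or a list/vector
#'   with elements `TP`, `FN`, `TN`, `FP`.
#' @return an object of class `metrics_report`: named numeric vector
#'   accessible as `$metrics` (`SEN`, `SPF`, `ACC`, `PPV`, `NPV`, `MCC`,
#'   `F1`) plus `$undefined` (names of flagged metrics) and `$cm`.
#' @export
#' @examples
#' compute_metrics(list(TP = 90, FN = 10, TN = 80, FP = 20))$metrics
compute_metrics <- function(cm) {
  cm <- as.list(cm)
  for (f in c("TP", "FN", "TN", "FP")) {
    assert(!is.null(cm[[f]]) && cm[[f]] >= 0, sprintf("missing count %s", f))
  }
  TP <- cm$TP; FN <- cm$FN; TN <- cm$TN; FP <- cm$FP
  total <- TP + FN + TN + FP
  assert(total > 0, "empty confusion matrix", class = "seizr_empty_input")
  ratio <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  mcc_den <- sqrt(prod(c(TP + FN, TP + FP, TN + FN, TN + FP)))
  m <- c(
    SEN = ratio(TP, TP + FN),
    SPF = ratio(TN, TN + FP),
    ACC = ratio(TP + TN, total),
    PPV = ratio(TP, TP + FP),
    NPV = ratio(TN, TN + FN),
    MCC = if (mcc_den > 0) 100 * (TP * TN - FN * FP) / mcc_den else NA_real_,
    F1 = ratio(2 * TP, 2 * TP + FN + FP)
  )
  undef <- names(m)[is.na(m)]
  if (length(undef)) {
    warning(sprintf("undefined metric(s) (zero denominator): %s",
                    paste(undef, collapse = ", ")))
  }
  structure(list(metrics = m, undefined = undef, cm = cm),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report (% scale)>\n")
  print(round(x$metrics, 2))
  if (length(x$undefined)) cat("undefined:", paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

#' Per-class one-vs-rest metrics from a multi-class confusion matrix
#'
#' For each class `c` the k x k count matrix (rows = truth, columns =
#' prediction) collapses to a binary matrix with `TP = m[c,c]`,
#' `FN = sum(m[c,-c])`, `FP = sum(m[-c,c])`, `TN` the rest; the macro average
#' is the unweighted mean over classes, skipping flagged-undefined values
#' (with a warning from the per-class computation).
#'
#' @param cm_k k x k integer matrix of counts.
#' @return list with `per_class` (list of [compute_metrics] reports) and
#'   `macro` (named numeric vector).
#' @export
one_vs_rest_metrics <- function(cm_k) {
  assert(is.matrix(cm_k) && nrow(cm_k) == ncol(cm_k) && nrow(cm_k) >= 2,
         "cm_k must be a square matrix with k >= 2")
  k <- nrow(cm_k)
  per_class <- vector("list", k)
  for (c in seq_len(k)) {
    TP <- cm_k[c, c]
    FN <- sum(cm_k[c, -c])
    FP <- sum(cm_k[-c, c])
    TN <- sum(cm_k) - TP - FN - FP
    per_class[[c]] <- compute_metrics(list(TP = TP, FN = FN, TN = TN, FP = FP))
  }
  names(per_class) <- rownames(cm_k) %||% paste0("class", seq_len(k) - 1L)
  mat <- do.call(rbind, lapply(per_class, function(r) r$metrics))
  macro <- colMeans(mat, na.rm = TRUE)
  list(per_class = per_class, macro = macro)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Multi-class confusion matrix of counts
#'
#' @param y_true,y_pred integer class ids in `[0, k)`.
#' @param k number of classes.
#' @return k x k matrix, rows = truth, columns = prediction.
#' @export
confusion_matrix_k <- function(y_true, y_pred, k = max(y_true, y_pred) + 1L) {
  m <- table(factor(y_true, levels = 0:(k - 1L)),
             factor(y_pred, levels = 0:(k - 1L)))
  matrix(as.integer(m), k, k, dimnames = list(rownames(m), colnames(m)))
}

#' Area under the ROC curve
#'
#' Computed as the normalized Mann-Whitney U statistic with midranks for
#' ties: the probability that a random positive scores above a random
#' negative (ties counting one half).
#'
#' @param y_true 0/1 labels (both classes must be present).
#' @param scores classifier scores, higher = more positive.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(y_true, scores) {
  assert(length(y_true) == length(scores), "length mismatch")
  n1 <- sum(y_true == 1)
  n0 <- sum(y_true == 0)
  assert(n1 > 0 && n0 > 0, "both classes must be present",
         class = "seizr_single_class")
  r <- rank(scores)  # midranks
  (sum(r[y_true == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Fold-wise statistical comparison of two models
#'
#' Paired two-sided Student's t-test and Wilcoxon signed-rank test on
#' per-fold accuracies, plus Cohen's d for paired data,
#' `d = mean(diff) / sd(diff)`. A zero-variance difference vector is flagged
#' as degenerate (the t statistic is undefined; the Wilcoxon p-value is 1 by
#' convention when all differences are zero).
#'
#' @param acc_a,acc_b per-fold metric vectors, paired by fold (length >= 5).
#' @return list with `t_p`, `wilcoxon_p`, `cohens_d`, `mean_diff`,
#'   `degenerate` (logical flag).
#' @export
compare_models <- function(acc_a, acc_b) {
  if (length(acc_a) != length(acc_b)) {
    abort("fold vectors must be paired (equal length)", "seizr_pairing_error")
  }
  assert(length(acc_a) >= 5, "need at least 5 folds for comparison")
  d <- acc_a - acc_b
  sdd <- stats::sd(d)
  if (sdd == 0) {
    return(list(t_p = NA_real_,
                wilcoxon_p = if (all(d == 0)) 1 else NA_real_,
                cohens_d = if (mean(d) == 0) 0 else Inf * sign(mean(d)),
                mean_diff = mean(d), degenerate = TRUE))
  }
  tt <- stats::t.test(acc_a, acc_b, paired = TRUE)
  wt <- suppressWarnings(stats::wilcox.test(acc_a, acc_b, paired = TRUE,
                                            exact = FALSE, correct = TRUE))
  list(t_p = unname(tt$p.value), wilcoxon_p = unname(wt$p.value),
       cohens_d = mean(d) / sdd, mean_diff = mean(d), degenerate = FALSE)
}

#' Evaluate hard predictions into a metrics report
#'
#' Binary tasks produce a single [compute_metrics] report; multi-class tasks
#' produce one-vs-rest per-class reports with macro averages (the macro
#' vector is returned as `$metrics` for a uniform interface).
#'
#' @param y_true,y_pred integer class ids.
#' @param n_classes number of classes.
#' @return a `metrics_report` (binary) or the [one_vs_rest_metrics] list
#'   with an added `$metrics` macro element.
#' @export
evaluate_predictions <- function(y_true, y_pred, n_classes = 2L) {
  if (n_classes == 2L) {
    compute_metrics(confusion_counts(y_true, y_pred))
  } else {
    ovr <- one_vs_rest_metrics(confusion_matrix_k(y_true, y_pred, n_classes))
    ovr$metrics <- ovr$macro
    ovr
  }
}
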