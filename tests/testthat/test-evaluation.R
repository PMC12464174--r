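test_that("the seven metrics match independent arithmetic to 4 decimals", {
  # expected values computed by hand from the ratio definitions
  m <- compute_metrics(list(TP = 90, FN = 10, TN = 80, FP = 20))$metrics
  expect_equal(unname(round(m, 2)),
               c(90.00, 80.00, 85.00, 81.82, 88.89, 70.35, 85.71))
  expect_equal(m[["PPV"]], 100 * 90 / 110, tolerance = 1e-10)
  expect_equal(m[["NPV"]], 100 * 80 / 90, tolerance = 1e-10)
  expect_equal(m[["F1"]], 100 * 180 / 210, tolerance = 1e-10)
  expect_equal(m[["MCC"]], 100 * (90 * 80 - 10 * 20) /
                 sqrt(100 * 110 * 90 * 100), tolerance = 1e-10)

  perfect <- compute_metrics(list(TP = 40, FN = 0, TN = 60, FP = 0))$metrics
  expect_equal(unname(perfect), rep(100, 7), tolerance = 1e-12)

  sym <- compute_metrics(list(TP = 25, FN = 25, TN = 25, FP = 25))$metrics
  expect_equal(sym[["MCC"]], 0, tolerance = 1e-12)
  expect_equal(sym[["ACC"]], 50, tolerance = 1e-12)
})

test_that("metrics are scale-invariant and MCC is swap-symmetric", {
  set.seed(21)
  for (i in 1:10) {
    cm <- as.list(sample(1:50, 4))
    names(cm) <- c("TP", "FN", "TN", "FP")
    m1 <- compute_metrics(cm)$metrics
    m2 <- compute_metrics(lapply(cm, `*`, 7L))$metrics
    expect_equal(m1, m2, tolerance = 1e-10)
    swapped <- compute_metrics(list(TP = cm$TN, FN = cm$FP,
                                    TN = cm$TP, FP = cm$FN))$metrics
    expect_equal(m1[["MCC"]], swapped[["MCC"]], tolerance = 1e-10)
  }
})

test_that("zero denominators are flagged, never silently zero", {
  expect_warning(r <- compute_metrics(list(TP = 0, FN = 0, TN = 10, FP = 5)))
  expect_true("SEN" %in% r$undefined)
  expect_true(is.na(r$metrics[["SEN"]]))
  expect_error(compute_metrics(list(TP = 0, FN = 0, TN = 0, FP = 0)),
               class = "seizr_empty_input")
})

test_that("one-vs-rest collapses agree with direct binary and brute force", {
  y_true <- c(rep(1L, 50), rep(0L, 50))
  y_pred <- c(rep(1L, 43), rep(0L, 7), rep(0L, 44), rep(1L, 6))
  bin <- compute_metrics(confusion_counts(y_true, y_pred))$metrics
  ovr <- one_vs_rest_metrics(confusion_matrix_k(y_true, y_pred, 2L))
  expect_equal(ovr$per_class[[2]]$metrics, bin, tolerance = 1e-10)

  diag3 <- diag(c(5L, 8L, 3L))
  all100 <- one_vs_rest_metrics(diag3)
  for (r in all100$per_class) expect_equal(unname(r$metrics), rep(100, 7))

  # fixed 3x3 example against explicit per-class tallies
  set.seed(8)
  yt <- sample(0:2, 120, replace = TRUE)
  yp <- ifelse(runif(120) < 0.7, yt, sample(0:2, 120, replace = TRUE))
  ovr3 <- one_vs_rest_metrics(confusion_matrix_k(yt, yp, 3L))
  for (cl in 0:2) {
    brute <- compute_metrics(list(
      TP = sum(yt == cl & yp == cl), FN = sum(yt == cl & yp != cl),
      TN = sum(yt != cl & yp != cl), FP = sum(yt != cl & yp == cl)))
    expect_equal(ovr3$per_class[[cl + 1]]$metrics, brute$metrics,
                 tolerance = 1e-10)
  }
})

test_that("ROC-AUC equals the midrank Mann-Whitney statistic", {
  y <- c(rep(0L, 5), rep(1L, 5))
  expect_identical(roc_auc(y, c(1:5, 6:10)), 1)
  expect_identical(roc_auc(y, rep(3, 10)), 0.5)

  set.seed(14)
  yy <- rbinom(100, 1, 0.4)
  s <- rnorm(100) + yy
  a1 <- roc_auc(yy, s)
  expect_equal(roc_auc(yy, exp(s)), a1, tolerance = 1e-12)   # monotone invariance
  expect_equal(roc_auc(yy, rank(s)), a1, tolerance = 1e-12)
  ref <- as.numeric(pROC::auc(pROC::roc(yy, s, quiet = TRUE,
                                        direction = "<")))
  expect_equal(a1, ref, tolerance = 1e-10)
  expect_error(roc_auc(rep(1L, 4), rnorm(4)), class = "seizr_single_class")
})

test_that("fold-wise comparison reproduces closed-form statistics", {
  a <- c(96.1, 97.3, 95.8, 96.9, 97.0, 96.2, 95.5, 97.8, 96.6, 96.4)
  b <- a - c(2.1, 1.6, 2.4, 1.9, 2.2, 1.8, 2.0, 2.3, 1.7, 2.0)
  res <- compare_models(a, b)
  d <- a - b
  expect_equal(res$cohens_d, mean(d) / sd(d), tolerance = 1e-12)
  expect_equal(res$t_p, t.test(a, b, paired = TRUE)$p.value,
               tolerance = 1e-12)
  expect_false(res$degenerate)

  # constructed fold vectors with known gap 2 and unit difference sd
  set.seed(3)
  diff <- rnorm(10)
  diff <- 2 + (diff - mean(diff)) / sd(diff)
  res2 <- compare_models(b + diff, b)
  expect_equal(res2$cohens_d, 2, tolerance = 1e-10)

  same <- compare_models(a, a)
  expect_true(same$degenerate)
  expect_identical(same$wilcoxon_p, 1)
  expect_identical(same$cohens_d, 0)

  shift <- compare_models(a + 1, a)
  expect_true(shift$degenerate)
  expect_identical(shift$cohens_d, Inf)

  expect_error(compare_models(a, a[1:5]), class = "seizr_pairing_error")
})
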