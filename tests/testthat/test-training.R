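test_that("stratified folds partition the data with exact class balance", {
  labels <- rep(c(0L, 1L), times = c(80L, 20L))
  folds <- stratified_folds(labels, 10L, seed = 3L)
  expect_length(folds, 10L)
  for (f in folds) expect_identical(sum(labels[f] == 1L), 2L)
  all_idx <- sort(unlist(folds))
  expect_identical(all_idx, seq_along(labels))              # cover
  expect_identical(sum(lengths(folds)), 100L)               # disjoint
})

test_that("uneven sample counts spread across folds within one sample", {
  labels <- rep(c(0L, 1L), times = c(50L, 47L))
  folds <- stratified_folds(labels, 10L, seed = 5L)
  sizes <- lengths(folds)
  expect_lte(max(sizes) - min(sizes), 1L)
  # per-fold positives within 1 of the proportional share
  pos <- vapply(folds, function(f) sum(labels[f] == 1L), 0L)
  expect_lte(max(pos) - min(pos), 1L)
})

test_that("a class smaller than k is a stratification error", {
  expect_error(stratified_folds(c(rep(0L, 20), 1L), 5L),
               class = "seizr_stratification_error")
})

test_that("fold assignment is a pure function of labels and seed", {
  labels <- rep(0:1, 25)
  expect_identical(stratified_folds(labels, 5L, seed = 9L),
                   stratified_folds(labels, 5L, seed = 9L))
})

test_that("inverse-frequency weights equalize class mass", {
  w <- class_weights(rep(c(0L, 1L), times = c(90L, 10L)))
  expect_equal(w, c(100 / 180, 5), tolerance = 1e-10)
  expect_identical(class_weights(rep(0:1, 10)), c(1, 1))
  w3 <- class_weights(rep(0:2, times = c(60L, 30L, 10L)))
  expect_equal(w3, c(100 / 180, 100 / 90, 100 / 30), tolerance = 1e-10)
  # weighted sample mass is equal across classes
  expect_equal(w3 * c(60, 30, 10), rep(100 / 3, 3), tolerance = 1e-10)
  expect_error(class_weights(c(0L, 0L, 2L)), class = "seizr_empty_class")
})

test_that("weighted loss reduces to unweighted when classes are balanced", {
  m <- build(tiny_spec(), seed = 1L)
  set.seed(4)
  x <- matrix(rnorm(8 * 24), 8)
  y <- rep(0:1, each = 4)
  fwd <- seizr:::nn_forward(m, x)
  a <- seizr:::.head_loss(m, fwd$logits, y, NULL)
  b <- seizr:::.head_loss(m, fwd$logits, y, class_weights(y))
  expect_identical(a$loss, b$loss)
  expect_identical(a$dlogits, b$dlogits)
})

test_that("cross-validation splits into the documented train/val/test shares", {
  ds <- generate_dataset(synthetic_spec(n_records = 200L, n_samples = 64L,
                                        seizure_fraction = 0.5, seed = 12L))
  feats <- featurize_dataset(ds, wavelet_config("db1", 2))
  cfg <- train_config(k_folds = 10L, val_split = 0.15, epochs = 1L,
                      lr = 1e-3, seed = 2L)
  cv <- quiet_cv(feats, cfg, spec_fn = function(n, k) tiny_spec_for(n, k))
  expect_length(cv$folds, 10L)
  for (fr in cv$folds) {
    expect_identical(length(fr$train_idx) + length(fr$val_idx) +
                       length(fr$test_idx), 200L)
    expect_length(intersect(fr$test_idx, c(fr$train_idx, fr$val_idx)), 0L)
    expect_lt(abs(length(fr$test_idx) / 200 - 0.10), 0.02)
    expect_lt(abs(length(fr$val_idx) / 200 - 0.135), 0.02)
    expect_lt(abs(length(fr$train_idx) / 200 - 0.765), 0.02)
    expect_identical(nrow(fr$history), 1L)
  }
  expect_named(cv$aggregate$mean,
               c("SEN", "SPF", "ACC", "PPV", "NPV", "MCC", "F1"))
})

test_that("chance-level data stays at chance under cross-validation", {
  # labels shuffled independently of the signal: accuracy ~ 50%
  ds <- generate_dataset(synthetic_spec(n_records = 60L, n_samples = 64L,
                                        seizure_fraction = 0.5, seed = 13L))
  feats <- featurize_dataset(ds, wavelet_config("db1", 2))
  set.seed(99)
  feats$y <- sample(feats$y)
  cfg <- train_config(k_folds = 3L, epochs = 5L, lr = 1e-3, seed = 3L)
  cv <- quiet_cv(feats, cfg, spec_fn = function(n, k) tiny_spec_for(n, k))
  expect_lt(abs(mean(cv$accuracies) - 50), 25)
})
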