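## Run configuration: a YAML document with four sections (dataset, features,
## training, output) validated against a fixed schema before any compute.

.schema <- list(
  dataset = c("source", "preset", "n_records", "n_channels", "n_samples",
              "fs", "seizure_fraction", "noise_sd"),
  features = c("kind", "wavelet", "level"),
  training = c("k_folds", "val_split", "lr", "batch_size", "epochs",
               "class_weighting"),
  output = c("dir"),
  top = c("dataset", "features", "training", "output", "seed")
)

#' Validate a run configuration
#'
#' Rejects unknown keys at every level and range-checks the numeric fields
#' (before any compute happens).
#'
#' @param cfg a nested list (e.g. from [yaml::read_yaml]).
#' @return the validated config, with defaults filled in.
#' @export
validate_config <- function(cfg) {
  bad <- setdiff(names(cfg), .schema$top)
  if (length(bad)) {
    abort(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")),
          "seizr_config_error")
  }
  for (sec in c("dataset", "features", "training", "output")) {
    bad <- setdiff(names(cfg[[sec]]), .schema[[sec]])
    if (length(bad)) {
      abort(sprintf("unknown key(s) in section '%s': %s", sec,
                    paste(bad, collapse = ", ")), "seizr_config_error")
    }
  }
  cfg$seed <- cfg$seed %||% 1L
  ds <- utils::modifyList(list(source = "synthetic", preset = "bonn",
                               n_records = 40L, seizure_fraction = 0.5),
                          cfg$dataset %||% list())
  ft <- utils::modifyList(list(kind = "dwt", wavelet = "db1", level = 3L),
                          cfg$features %||% list())
  tr <- utils::modifyList(list(k_folds = 5L, val_split = 0.15, lr = 1e-3,
                               batch_size = 60L, epochs = 20L,
                               class_weighting = "inverse_frequency"),
                          cfg$training %||% list())
  if (!identical(ds$source, "synthetic")) {
    abort("only source: synthetic is supported by run_pipeline",
          "seizr_config_error")
  }
  if (!ft$kind %in% c("dwt", "raw")) {
    abort(sprintf("unknown feature kind '%s'", ft$kind), "seizr_config_error")
  }
  if (!is.numeric(tr$val_split) || tr$val_split <= 0 || tr$val_split >= 1) {
    abort("training.val_split must lie in (0, 1)", "seizr_config_error")
  }
  if (!is.null(ds$seizure_fraction) &&
      (ds$seizure_fraction < 0 || ds$seizure_fraction > 1)) {
    abort("dataset.seizure_fraction must lie in [0, 1]", "seizr_config_error")
  }
  list(dataset = ds, features = ft, training = tr,
       output = cfg$output %||% list(dir = tempfile("seizr_run_")),
       seed = cfg$seed)
}

#' Run the full pipeline from a configuration
#'
#' Generates the synthetic dataset described by the config, extracts
#' features, runs class-weighted stratified cross-validation of the default
#' CNN-LSTM, and writes a reproducible run directory: the config snapshot
#' (`config.yaml`), fold assignments (`folds.csv`), per-fold metrics
#' (`fold_metrics.csv`), aggregate metrics (`aggregate.json`) and a manifest
#' (`manifest.json` with package/R versions and stage timings).
#'
#' @param config path to a YAML file or a nested list.
#' @return invisibly, a list with the run `dir`, the `cv` result and the
#'   aggregate metrics.
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  cfg <- validate_config(cfg)
  dir.create(cfg$output$dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  timings <- list()

  preset_args <- cfg$dataset[setdiff(names(cfg$dataset), c("source", "preset"))]
  spec <- do.call(synthetic_preset,
                  c(list(preset = cfg$dataset$preset, seed = cfg$seed),
                    preset_args))
  ds <- generate_dataset(spec)
  timings$simulate <- as.numeric(Sys.time() - t0, units = "secs")

  t1 <- Sys.time()
  feats <- if (cfg$features$kind == "dwt") {
    featurize_dataset(ds, wavelet_config(cfg$features$wavelet,
                                         cfg$features$level))
  } else {
    featurize_dataset(ds, NULL)
  }
  timings$featurize <- as.numeric(Sys.time() - t1, units = "secs")

  t2 <- Sys.time()
  tc <- train_config(k_folds = cfg$training$k_folds,
                     val_split = cfg$training$val_split,
                     lr = cfg$training$lr,
                     batch_size = cfg$training$batch_size,
                     epochs = cfg$training$epochs,
                     class_weighting = cfg$training$class_weighting,
                     seed = cfg$seed)
  cv <- run_cv(feats, tc)
  timings$train <- as.numeric(Sys.time() - t2, units = "secs")

  yaml::write_yaml(cfg, file.path(cfg$output$dir, "config.yaml"))
  folds_df <- do.call(rbind, lapply(cv$folds, function(fr) {
    data.frame(fold = fr$fold, index = fr$test_idx)
  }))
  utils::write.csv(folds_df, file.path(cfg$output$dir, "folds.csv"),
                   row.names = FALSE)
  fm <- do.call(rbind, lapply(cv$folds, function(fr) {
    data.frame(fold = fr$fold, t(fr$report$metrics))
  }))
  utils::write.csv(fm, file.path(cfg$output$dir, "fold_metrics.csv"),
                   row.names = FALSE)
  agg <- list(mean = as.list(cv$aggregate$mean), sd = as.list(cv$aggregate$sd))
  jsonlite::write_json(agg, file.path(cfg$output$dir, "aggregate.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest <- list(
    seed = cfg$seed,
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("seizr")),
    timings_s = timings,
    n_windows = length(ds),
    feature_length = ncol(feats$x)
  )
  jsonlite::write_json(manifest, file.path(cfg$output$dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(dir = cfg$output$dir, cv = cv, aggregate = agg))
}
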