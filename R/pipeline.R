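# End-to-end pipeline: simulate -> segment -> encode -> split -> train ->
# evaluate, with one global seed and a provenance manifest.

#' Pipeline configuration
#'
#' One object carrying every stage's parameters. The defaults describe the
#' package's desk-scale benchmark: the development corpus's class
#' proportions at 1% scale, 2000-sample segments, 64 x 64 GASF images, the
#' improved variant at reduced depth (one block per stage) and quarter
#' width, and a short Adam schedule (learning rate 5e-4, batch 16, 18
#' epochs -- the budget at which the benchmark's loss reaches its floor;
#' full-scale training keeps the classical 1e-4 / batch 32 / 150 epochs of
#' [train_config()]).
#'
#' @param class_counts named per-class segment counts.
#' @param segment_len segment length in samples.
#' @param fs sampling frequency (Hz).
#' @param image_size GASF image side in pixels.
#' @param variant `"baseline-relu"`, `"improved-relu"` or `"improved-selu"`.
#' @param block_plan residual blocks per stage.
#' @param width channel-width multiplier.
#' @param ratio train fraction of the stratified split.
#' @param train a [train_config()]; its seed is overridden by `seed`.
#' @param seed global seed propagated to every stage.
#' @param out_dir optional directory for artifacts (manifest, split,
#'   history, confusion matrix, metrics, provenance).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(class_counts = round(reference_class_counts() * 0.01),
                            segment_len = 2000L, fs = 360,
                            image_size = 64L,
                            variant = "improved-selu",
                            block_plan = c(1, 1, 1, 1),
                            width = 0.25,
                            ratio = 0.8,
                            train = train_config(learning_rate = 5e-4,
                                                 batch_size = 16L,
                                                 epochs = 18L),
                            seed = 1L,
                            out_dir = NULL) {
  train$seed <- as.integer(seed)
  structure(list(class_counts = class_counts,
                 segment_len = as.integer(segment_len), fs = fs,
                 image_size = as.integer(image_size), variant = variant,
                 block_plan = block_plan, width = width, ratio = ratio,
                 train = train, seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

config_hash <- function(cfg) {
  flat <- unlist(cfg[setdiff(names(cfg), "out_dir")])
  hash_string(paste(names(flat), format(flat, digits = 15), sep = "=",
                    collapse = ";"))
}

#' Package version, seed and configuration hash for a run
#'
#' @param cfg a [pipeline_config()].
#' @return List with `package`, `version`, `r_version`, `config_hash`,
#'   `seed`, `timestamp`.
#' @export
version_and_provenance <- function(cfg) {
  list(package = "gasfnet",
       version = as.character(utils::packageVersion("gasfnet")),
       r_version = paste(R.version$major, R.version$minor, sep = "."),
       config_hash = config_hash(cfg),
       seed = cfg$seed,
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

#' Run the full pipeline
#'
#' Simulates the synthetic dataset, encodes segments as GASF images, makes
#' the stratified split, trains the configured variant, and evaluates on
#' the held-out set. Deterministic given `cfg$seed`. When `cfg$out_dir` is
#' set, writes `manifest.csv`, `split.csv`, `history.csv`, `confusion.csv`,
#' `metrics.csv` and `provenance.txt` there.
#'
#' @param cfg a [pipeline_config()].
#' @param verbose print per-epoch training progress.
#' @return Object of class `gasfnet_run`: list with `report`
#'   (an [evaluation_report()]), `fit`, `split`, `dataset` manifest, and
#'   `provenance`.
#' @export
run_pipeline <- function(cfg = pipeline_config(), verbose = FALSE) {
  ds <- make_dataset(cfg$class_counts, cfg$segment_len, cfg$fs, seed = cfg$seed)
  enc <- encode_segments(ds$segments, size = cfg$image_size)
  split <- stratified_split(enc$y, ratio = cfg$ratio, seed = cfg$seed)
  classes <- intersect(arrhythmia_classes(), unique(enc$y))
  data <- list(x = enc$x[, , , split$train_indices, drop = FALSE],
               y = enc$y[split$train_indices],
               x_test = enc$x[, , , split$test_indices, drop = FALSE],
               y_test = enc$y[split$test_indices])
  spec <- variant_spec(cfg$variant, n_classes = length(classes),
                       block_plan = cfg$block_plan, width = cfg$width)
  fit <- train_model(spec, data, cfg$train, classes = classes,
                     verbose = verbose)
  pred <- predict(fit, data$x_test)
  report <- evaluation_report(confusion_matrix(data$y_test, pred, classes))
  prov <- version_and_provenance(cfg)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(ds$manifest, file.path(cfg$out_dir, "manifest.csv"),
              row.names = FALSE)
    write.csv(data.frame(index = c(split$train_indices, split$test_indices),
                         set = rep(c("train", "test"),
                                   c(length(split$train_indices),
                                     length(split$test_indices)))),
              file.path(cfg$out_dir, "split.csv"), row.names = FALSE)
    write.csv(fit$history, file.path(cfg$out_dir, "history.csv"),
              row.names = FALSE)
    write_report(report, cfg$out_dir)
    writeLines(sprintf("%s: %s", names(prov), unlist(prov)),
               file.path(cfg$out_dir, "provenance.txt"))
  }
  structure(list(report = report, fit = fit, split = split,
                 dataset = ds$manifest, provenance = prov),
            class = "gasfnet_run")
}

#' @export
print.gasfnet_run <- function(x, ...) {
  cat(sprintf("<gasfnet_run: seed %d, config %s>\n", x$provenance$seed,
              substr(x$provenance$config_hash, 1, 8)))
  print(x$report)
  invisible(x)
}
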