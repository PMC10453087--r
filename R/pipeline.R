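#' Simulate a dataset to disk
#'
#' Generates the synthetic mixture dataset and writes `spectra.csv` (long
#' format, [write_spectra()]) and `manifest.json` ([write_manifest()]) into
#' `out_dir`.
#'
#' @param out_dir Output directory (created if missing).
#' @param config A [generator_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @param quiet Suppress the class-count message.
#' @return Invisibly, a list with `spectra` and `manifest` paths and the
#'   generated dataset.
#' @export
run_simulate <- function(out_dir, config = generator_config(),
                         seed = config$seed, quiet = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    stop(sprintf("run_simulate: cannot create output directory %s", out_dir))
  ds <- generate_dataset(config, seed = seed)
  mat <- dataset_matrix(ds)
  spectra_path <- file.path(out_dir, "spectra.csv")
  manifest_path <- file.path(out_dir, "manifest.json")
  write_spectra(unlist(lapply(ds, `[[`, "spectra"), recursive = FALSE),
                spectra_path)
  counts <- table(mat$labels)
  write_manifest(manifest_path, files = "spectra.csv",
                 classes = names(config$classes), seed = seed,
                 config = config, counts = counts)
  if (!quiet)
    message(sprintf("simulated %d spectra (%s)", nrow(mat$x),
                    paste(sprintf("%s: %d", names(counts), counts),
                          collapse = ", ")))
  invisible(list(spectra = spectra_path, manifest = manifest_path,
                 dataset = ds))
}

# Spectra sharing one uniform grid are used as-is; heterogeneous grids are
# resampled onto the default 751-point grid (or `input_length` points).
.load_dataset_matrix <- function(dataset_path, input_length = 751) {
  spectra <- read_spectra(dataset_path)
  if (length(spectra) == 0)
    stop(sprintf("no spectra in %s", dataset_path))
  g1 <- spectra[[1]]$grid
  same <- vapply(spectra, function(s)
    s$grid$n_points == g1$n_points &&
      isTRUE(all.equal(s$grid$start, g1$start)) &&
      isTRUE(all.equal(s$grid$stop, g1$stop)), TRUE)
  if (!all(same))
    spectra <- lapply(spectra, resample_spectrum,
                      target = wavenumber_grid(n_points = input_length))
  dataset_matrix(spectra)
}

#' Train a network on a dataset file
#'
#' Reads spectra (resampling onto the default grid when needed), splits them
#' per the 30% / 3:1 protocol, builds the requested architecture and trains
#' it. Writes `checkpoint.rds`, `history.csv`, `split.json` and `audit.json`
#' into `out_dir`.
#'
#' @param dataset_path CSV of labelled spectra ([read_spectra()] formats).
#' @param architecture One of `"squeezenet1d"`, `"mobilenet1d"`,
#'   `"shufflenet1d"`.
#' @param out_dir Output directory.
#' @param seed Seed used for the split, weight init and training.
#' @param epochs,batch_size,lr,patience Training hyperparameters
#'   (see [train_network()]).
#' @param quiet Suppress progress messages.
#' @return Invisibly, list with the `sersnet_fit` and output paths.
#' @export
run_train <- function(dataset_path, architecture, out_dir, seed = 1,
                      epochs = 200, batch_size = 32, lr = 1e-3,
                      patience = 30, quiet = FALSE) {
  architectures <- c("squeezenet1d", "mobilenet1d", "shufflenet1d")
  if (!architecture %in% architectures)
    stop(sprintf("unknown architecture '%s'; valid: %s", architecture,
                 paste(architectures, collapse = ", ")))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  mat <- .load_dataset_matrix(dataset_path)
  if (anyNA(mat$labels) || any(mat$labels == "NA"))
    stop("run_train: dataset has unlabelled spectra")
  split <- split_dataset(mat$labels, seed = seed)
  model <- build_network(network_config(architecture,
                                        input_length = ncol(mat$x),
                                        n_classes = nlevels(mat$labels),
                                        seed = seed))
  fit <- train_network(model, mat$x, mat$labels, split, epochs = epochs,
                       batch_size = batch_size, lr = lr, patience = patience,
                       seed = seed, verbose = !quiet)
  ckpt <- file.path(out_dir, "checkpoint.rds")
  saveRDS(fit, ckpt)
  jsonlite::write_json(list(dataset = dataset_path,
                            architecture = architecture, seed = seed,
                            epochs = epochs, batch_size = batch_size,
                            lr = lr, patience = patience,
                            package_version =
                              as.character(utils::packageVersion("sersnet"))),
                       file.path(out_dir, "params.json"), auto_unbox = TRUE,
                       digits = NA)
  utils::write.csv(fit$history, file.path(out_dir, "history.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(seed = seed,
                            training = split$training,
                            validation = split$validation,
                            prediction = split$prediction),
                       file.path(out_dir, "split.json"), auto_unbox = TRUE)
  jsonlite::write_json(model_audit(fit$model),
                       file.path(out_dir, "audit.json"),
                       auto_unbox = TRUE, dataframe = "rows", digits = NA)
  if (!quiet)
    message(sprintf("trained %s: best epoch %d, acc_V %.2f%%", architecture,
                    fit$best_epoch,
                    fit$history$acc_val[fit$best_epoch]))
  invisible(list(fit = fit, checkpoint = ckpt, out_dir = out_dir))
}

#' Evaluate a checkpoint on a dataset
#'
#' Loads a trained checkpoint, re-reads the dataset, evaluates on the
#' recorded split and writes `report.json`, `report.csv` and
#' `confusion_<subset>.csv` into `out_dir`. The split stored with the
#' checkpoint (or an explicit `split.json`) is required — the data are never
#' silently re-split.
#'
#' @param checkpoint Path to a `checkpoint.rds` from [run_train()].
#' @param dataset_path Spectra CSV the checkpoint was trained on.
#' @param out_dir Output directory.
#' @param split_path Optional `split.json` overriding the stored split.
#' @param quiet Suppress the summary line.
#' @return Invisibly, the `sersnet_evaluation`.
#' @export
run_evaluate <- function(checkpoint, dataset_path, out_dir,
                         split_path = NULL, quiet = FALSE) {
  if (!file.exists(checkpoint))
    stop(sprintf("checkpoint not found: %s", checkpoint))
  fit <- readRDS(checkpoint)
  stopifnot(inherits(fit, "sersnet_fit"))
  split <- fit$split
  if (!is.null(split_path)) {
    sj <- jsonlite::read_json(split_path, simplifyVector = TRUE)
    split <- structure(list(training = sj$training,
                            validation = sj$validation,
                            prediction = sj$prediction, seed = sj$seed),
                       class = "sersnet_split")
  }
  if (is.null(split))
    stop("run_evaluate: no split record available; refusing to re-split")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  mat <- .load_dataset_matrix(dataset_path, fit$model$input_length)
  ev <- evaluate_network(fit, mat$x, mat$labels, split)
  rep_list <- list(architecture = fit$model$config$architecture,
                   seed = fit$seed,
                   acc_t = ev$acc[["acc_t"]], acc_v = ev$acc[["acc_v"]],
                   acc_p = ev$acc[["acc_p"]],
                   per_class = ev$prediction$per_class,
                   confusion_matrix = unclass(ev$prediction$confusion),
                   prediction = report_to_list(ev$prediction))
  jsonlite::write_json(rep_list, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, dataframe = "rows", digits = NA)
  utils::write.csv(ev$prediction$per_class,
                   file.path(out_dir, "report.csv"), row.names = FALSE)
  for (sub in c("training", "validation", "prediction"))
    utils::write.csv(ev[[sub]]$confusion,
                     file.path(out_dir, sprintf("confusion_%s.csv", sub)))
  if (!quiet)
    message(sprintf("ACC_T = %.2f%%  ACC_V = %.2f%%  ACC_P = %.2f%%",
                    ev$acc[["acc_t"]], ev$acc[["acc_v"]], ev$acc[["acc_p"]]))
  invisible(ev)
}
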