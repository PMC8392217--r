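#' @name run-drivers
#' @title Reproducible run drivers
#' @description Thin orchestration over the package's functions:
#' simulate a dataset, featurize it, train, evaluate, cross-validate.
#' Every run writes its resolved configuration, seed and package
#' version into the output directory so any artifact on disk is
#' regenerable from (inputs, configuration, seed). The companion
#' command-line script (`inst/scripts/cpiconv-cli.R`) exposes these as
#' shell subcommands.
#' @keywords internal
NULL

#' Load a run configuration file
#'
#' A flat JSON key-value file whose keys are [cpi_config()] fields
#' plus the run-level keys `profile`, `seed`, `ratio`, `folds`,
#' `ablate`, `noise`, `n_targets`, `molecules_per_target`. Unknown
#' keys are rejected. CLI/function arguments override file values.
#'
#' @param file JSON path, or `NULL` for pure defaults.
#' @param overrides named list applied on top of the file.
#' @return List with `config` (a [cpi_config()]) and the run-level
#'   settings.
#' @export
load_run_config <- function(file = NULL, overrides = list()) {
  run_defaults <- list(profile = "default", seed = 1L, ratio = 1L,
                       folds = 5L, ablate = "none", noise = 0,
                       n_targets = 10L, molecules_per_target = 40L)
  vals <- list()
  if (!is.null(file))
    vals <- jsonlite::read_json(file, simplifyVector = TRUE)
  vals[names(overrides)] <- overrides
  known <- c(names(run_defaults), names(cpi_config()))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  run <- run_defaults
  run[intersect(names(vals), names(run_defaults))] <-
    vals[intersect(names(vals), names(run_defaults))]
  cfg_over <- vals[intersect(names(vals), names(cpi_config()))]
  run$config <- do.call(cpi_config, c(list(profile = run$profile),
                                      cfg_over))
  run
}

write_run_record <- function(dir, run, extra = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rec <- c(list(package_version =
                  as.character(utils::packageVersion("cpiconv")),
                timestamp = format(Sys.time(), tz = "UTC"),
                seed = run$seed,
                config = unclass(run$config),
                run = run[setdiff(names(run), "config")]),
           extra)
  jsonlite::write_json(rec, file.path(dir, "run_record.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Simulate a synthetic dataset to disk
#'
#' @param out_dir output directory.
#' @param run run settings from [load_run_config()] (or its default).
#' @return `out_dir` invisibly.
#' @export
run_simulate <- function(out_dir, run = load_run_config()) {
  tg <- generate_targets(run$n_targets, seed = run$seed)
  rule <- planted_rule(noise = run$noise)
  pr <- generate_pairs(tg, run$molecules_per_target, run$ratio,
                       rule, seed = run$seed + 1L)
  write_synthetic_dataset(tg, pr, out_dir)
  write_run_record(out_dir, run)
  invisible(out_dir)
}

#' Featurize a dataset directory
#'
#' Reads a dataset written by [write_synthetic_dataset()] (or
#' hand-assembled in the same formats), builds the site grids and
#' token vectors, and writes a grid container plus a token TSV. The
#' step is idempotent: outputs are keyed by the MD5 of the inputs and
#' an unchanged rerun is a cache hit.
#'
#' @param data_dir dataset directory.
#' @param out_dir output directory.
#' @param run run settings.
#' @return `out_dir` invisibly.
#' @export
run_featurize <- function(data_dir, out_dir,
                          run = load_run_config()) {
  ds <- read_synthetic_dataset(data_dir)
  if (nrow(ds$pairs) == 0) warning("empty pairs file", call. = FALSE)
  ins <- sort(list.files(data_dir, full.names = TRUE))
  key <- unname(tools::md5sum(ins))
  keyfile <- file.path(out_dir, "featurize_manifest.json")
  if (file.exists(keyfile)) {
    old <- jsonlite::read_json(keyfile, simplifyVector = TRUE)
    if (identical(unname(old$input_md5), key)) {
      message("featurization up to date (cache hit)")
      return(invisible(out_dir))
    }
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tc <- featurize_targets(ds$targets, run$config)
  n <- run$config$grid_edge / run$config$grid_resolution
  grids <- lapply(tc, function(t)
    array(t(t$V), dim = c(run$config$grid_channels, n, n, n)))
  for (g in seq_along(grids)) {
    attr(grids[[g]], "spec") <- list(edge = run$config$grid_edge,
                                     resolution = run$config$grid_resolution,
                                     n = n)
    attr(grids[[g]], "channels") <- CHANNEL_NAMES
  }
  write_grids(grids, file.path(out_dir, "grids.bin"))
  tok <- do.call(rbind, lapply(names(tc), function(t)
    data.frame(target_id = t,
               tokens = paste(tc[[t]]$tokens, collapse = ","))))
  utils::write.table(tok, file.path(out_dir, "tokens.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(input_md5 = key, inputs = basename(ins)),
                       keyfile, auto_unbox = TRUE, digits = NA)
  write_run_record(out_dir, run)
  invisible(out_dir)
}

#' Train a model on a dataset directory
#'
#' Fits [cpi_fit()] on the dataset's pairs and writes a checkpoint,
#' the per-epoch training log and the resolved run record.
#'
#' @param data_dir dataset directory.
#' @param out_dir output directory.
#' @param run run settings (`run$ablate` selects pathway ablations).
#' @param validation optional pairs data frame for per-epoch AUC.
#' @param verbose print per-epoch progress.
#' @return The fitted model, invisibly.
#' @export
run_train <- function(data_dir, out_dir, run = load_run_config(),
                      validation = NULL, verbose = TRUE) {
  ds <- read_synthetic_dataset(data_dir)
  fit <- cpi_fit(ds$pairs, ds$targets, ds$molecules, run$config,
                 validation = validation, ablate = run$ablate,
                 seed = run$seed, verbose = verbose)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  save_checkpoint(fit, file.path(out_dir, "checkpoint.bin"))
  utils::write.table(fit$history, file.path(out_dir, "training_log.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_run_record(out_dir, run)
  invisible(fit)
}

#' Evaluate a checkpoint on a dataset directory
#'
#' Loads a checkpoint, scores the dataset's pairs and writes the full
#' evaluation report (overall AUC, per-target AUC TSV, strict
#' threshold counts, best-F1 metrics) plus a predictions TSV
#' (target_id, ligand_id, probability).
#'
#' @param checkpoint checkpoint path from [run_train()].
#' @param data_dir dataset directory.
#' @param out_dir output directory.
#' @return The `"cpi_eval"` report, invisibly.
#' @export
run_evaluate <- function(checkpoint, data_dir, out_dir) {
  fit <- load_checkpoint(checkpoint)
  ds <- read_synthetic_dataset(data_dir)
  p <- predict(fit, ds$pairs, targets = ds$targets,
               molecules = ds$molecules)
  rep <- eval_report(ds$pairs, p)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_eval_report(rep, out_dir)
  utils::write.table(
    data.frame(target_id = ds$pairs$target_id,
               ligand_id = ds$pairs$ligand_id, probability = p),
    file.path(out_dir, "predictions.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(rep)
}

#' Cross-validate on a dataset directory
#'
#' @param data_dir dataset directory.
#' @param out_dir output directory.
#' @param run run settings (`run$folds` folds).
#' @param verbose print per-epoch progress.
#' @return The `"cpi_cv"` result, invisibly.
#' @export
run_cv <- function(data_dir, out_dir, run = load_run_config(),
                   verbose = FALSE) {
  ds <- read_synthetic_dataset(data_dir)
  cv <- kfold_cv(ds$pairs, ds$targets, ds$molecules, run$config,
                 k = run$folds, seed = run$seed, ablate = run$ablate,
                 verbose = verbose)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(list(fold_auc = cv$fold_auc,
                            mean_auc = cv$mean_auc, k = cv$k,
                            seed = cv$seed),
                       file.path(out_dir, "cv.json"),
                       auto_unbox = TRUE, digits = NA)
  write_run_record(out_dir, run)
  invisible(cv)
}
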