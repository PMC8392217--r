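#' @name data-eval
#' @title Dataset assembly and virtual-screening evaluation
#' @description Datasets pair each target's known actives (label 1)
#' with sampled decoys (label 0) at a controlled positive:negative
#' ratio; train/test splits are target-disjoint so no protein leaks
#' across sides. Screening quality is summarized by overall and
#' per-target ROC AUC (Mann-Whitney convention, ties counted one
#' half), counts of targets whose AUC exceeds 0.7/0.8/0.9 (strict),
#' and precision/recall/F1 at the threshold maximizing F1.
#' @keywords internal
NULL

#' Assemble active/decoy sample pairs per target
#'
#' For every target: all actives are labeled 1 and `ratio` decoys per
#' active are drawn at random (seeded) and labeled 0, so a fully
#' supplied target contributes `(ratio + 1) * n_actives` pairs.
#' Targets with fewer decoys than requested use all they have, with a
#' warning; targets without actives are excluded with a warning.
#'
#' @param actives named list: per target, a character vector of active
#'   ligand ids.
#' @param decoys named list: per target, a character vector of decoy
#'   ligand ids.
#' @param ratio decoys per active (integer `>= 1`).
#' @param seed seed for the decoy draw.
#' @return Data frame with `target_id`, `ligand_id`, `label`.
#' @examples
#' assemble_pairs(list(t1 = "a1"), list(t1 = c("d1", "d2", "d3")),
#'                ratio = 2, seed = 1)
#' @export
assemble_pairs <- function(actives, decoys, ratio = 1L, seed = 1L) {
  stopifnot(ratio >= 1, !is.null(names(actives)))
  out <- with_seed(seed, {
    res <- lapply(names(actives), function(t) {
      act <- actives[[t]]
      if (!length(act)) {
        warning("target ", t, " has no actives; excluded", call. = FALSE)
        return(NULL)
      }
      dec <- decoys[[t]]
      want <- length(act) * ratio
      if (length(dec) < want) {
        warning("target ", t, ": only ", length(dec), " decoys for ",
                want, " requested; using all", call. = FALSE)
        pick <- dec
      } else {
        pick <- sample(dec, want)
      }
      data.frame(target_id = t, ligand_id = c(act, pick),
                 label = rep(c(1L, 0L), c(length(act), length(pick))),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
  })
  rownames(out) <- NULL
  out
}

#' Split sample pairs by protein target
#'
#' Target-disjoint train/test split: every pair follows its protein,
#' so no target appears on both sides.
#'
#' @param pairs data frame of sample pairs.
#' @param train_targets,test_targets disjoint character vectors of
#'   target ids.
#' @return List of class `"dataset_split"` with `train` and `test`
#'   pair data frames and the two target vectors.
#' @export
split_by_target <- function(pairs, train_targets, test_targets) {
  if (length(intersect(train_targets, test_targets)))
    stop("train and test target sets overlap", call. = FALSE)
  pairs <- check_pairs(pairs)
  out <- list(train = pairs[pairs$target_id %in% train_targets, ,
                            drop = FALSE],
              test = pairs[pairs$target_id %in% test_targets, ,
                           drop = FALSE],
              train_targets = train_targets,
              test_targets = test_targets)
  class(out) <- "dataset_split"
  out
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split: %d train pairs over %d targets | %d test pairs over %d targets>\n",
              nrow(x$train), length(x$train_targets),
              nrow(x$test), length(x$test_targets)))
  invisible(x)
}

#' ROC AUC by pairwise concordance
#'
#' The probability that a randomly chosen positive is scored above a
#' randomly chosen negative, with ties counted one half (the
#' Mann-Whitney U formulation of the area under the ROC curve),
#' computed from the rank sum.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels.
#' @return AUC in `[0, 1]`.
#' @examples
#' roc_auc(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0))   # 0.75
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels),
            all(labels %in% c(0, 1)))
  P <- sum(labels == 1); N <- sum(labels == 0)
  if (P == 0 || N == 0)
    stop("AUC undefined: both classes must be present", call. = FALSE)
  r <- rank(scores)
  (sum(r[labels == 1]) - P * (P + 1) / 2) / (P * N)
}

#' Per-target ROC AUC and threshold counting
#'
#' Computes the AUC separately for each target and counts targets
#' whose AUC strictly exceeds 0.7, 0.8 and 0.9. Targets with only one
#' class among their pairs cannot be scored and are excluded with a
#' warning.
#'
#' @param pairs data frame of sample pairs (with labels).
#' @param scores prediction scores aligned with `pairs` rows.
#' @param thresholds AUC thresholds for the counting (default
#'   `c(0.7, 0.8, 0.9)`).
#' @return List with `auc` (named per-target vector), `counts` (named
#'   integer vector of strict exceedances), and `excluded` (ids of
#'   unscorable targets).
#' @export
per_target_auc <- function(pairs, scores,
                           thresholds = c(0.7, 0.8, 0.9)) {
  stopifnot(nrow(pairs) == length(scores))
  tids <- unique(pairs$target_id)
  auc <- numeric(0); excluded <- character(0)
  for (t in tids) {
    i <- pairs$target_id == t
    y <- pairs$label[i]
    if (length(unique(y)) < 2) {
      excluded <- c(excluded, t)
      next
    }
    auc[t] <- roc_auc(scores[i], y)
  }
  if (length(excluded))
    warning("single-class target(s) excluded from per-target AUC: ",
            paste(excluded, collapse = ", "), call. = FALSE)
  counts <- vapply(thresholds, function(th) sum(auc > th), 0L)
  names(counts) <- paste0(">", thresholds)
  list(auc = auc, counts = counts, excluded = excluded)
}

#' Best-F1 classification threshold
#'
#' Scans every distinct score (plus the 0 and 1 endpoints) as a
#' candidate threshold, classifying `score >= threshold` as positive,
#' and returns the threshold maximizing the F1-score; ties break
#' toward the lower threshold. Precision is taken as 1 when nothing is
#' predicted positive (zero false positives).
#'
#' @param scores prediction scores.
#' @param labels 0/1 labels (both classes required).
#' @return List with `threshold`, `precision`, `recall`, `f1`.
#' @export
best_f1_threshold <- function(scores, labels) {
  stopifnot(length(scores) == length(labels),
            all(labels %in% c(0, 1)))
  if (length(unique(labels)) < 2)
    stop("both classes must be present", call. = FALSE)
  cand <- sort(unique(c(0, scores, 1)))
  best <- list(threshold = NA_real_, precision = NA_real_,
               recall = NA_real_, f1 = -1)
  for (th in cand) {
    pred <- scores >= th
    tp <- sum(pred & labels == 1)
    fp <- sum(pred & labels == 0)
    fn <- sum(!pred & labels == 1)
    prec <- if (tp + fp == 0) 1 else tp / (tp + fp)
    rec <- tp / (tp + fn)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    if (f1 > best$f1)
      best <- list(threshold = th, precision = prec, recall = rec,
                   f1 = f1)
  }
  best
}

#' Full evaluation report
#'
#' Overall AUC, per-target AUC with strict threshold counts, and
#' precision/recall/F1 at the best-F1 threshold, for one set of
#' predictions.
#'
#' @param pairs data frame of evaluated sample pairs.
#' @param scores prediction scores aligned with `pairs`.
#' @return List of class `"cpi_eval"`.
#' @export
eval_report <- function(pairs, scores) {
  pt <- suppressWarnings(per_target_auc(pairs, scores))
  bf <- best_f1_threshold(scores, pairs$label)
  structure(list(auc = roc_auc(scores, pairs$label),
                 per_target = pt$auc, counts = pt$counts,
                 excluded = pt$excluded,
                 threshold = bf$threshold, precision = bf$precision,
                 recall = bf$recall, f1 = bf$f1,
                 n_pairs = nrow(pairs),
                 n_targets = length(unique(pairs$target_id))),
            class = "cpi_eval")
}

#' @export
print.cpi_eval <- function(x, ...) {
  cat(sprintf("CPI evaluation over %d pairs / %d targets\n",
              x$n_pairs, x$n_targets))
  cat(sprintf("  overall AUC %.4f\n", x$auc))
  cat(sprintf("  targets with AUC %s: %s\n",
              paste(names(x$counts), collapse = " / "),
              paste(x$counts, collapse = " / ")))
  cat(sprintf("  best-F1 threshold %.3f: precision %.3f, recall %.3f, F1 %.3f\n",
              x$threshold, x$precision, x$recall, x$f1))
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' JSON (machine-readable), a text summary, and the per-target AUC as
#' TSV.
#'
#' @param report a `"cpi_eval"`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_eval_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(auc = report$auc, counts = as.list(report$counts),
         threshold = report$threshold, precision = report$precision,
         recall = report$recall, f1 = report$f1,
         n_pairs = report$n_pairs, n_targets = report$n_targets),
    file.path(dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
  utils::write.table(
    data.frame(target_id = names(report$per_target),
               auc = unname(report$per_target)),
    file.path(dir, "per_target_auc.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  con <- file(file.path(dir, "metrics.txt"), "w")
  sink(con); print(report); sink()
  close(con)
  invisible(dir)
}

#' Target-disjoint k-fold cross-validation
#'
#' Partitions the training targets (not the pairs) into k folds,
#' trains on k-1 folds and evaluates AUC on the held-out fold's pairs,
#' cycling through all folds. Fold assignment is seeded and
#' reproducible.
#'
#' @param pairs training sample pairs.
#' @param targets,molecules as in [cpi_fit()].
#' @param config a [cpi_config()].
#' @param k number of folds (default 5).
#' @param seed seed for fold assignment (fed, per fold, into the fit).
#' @param ... passed on to [cpi_fit()] (e.g. `ablate`,
#'   `verbose`).
#' @return List of class `"cpi_cv"`: `fold_auc` (length k), `mean_auc`,
#'   and `folds` (the target assignment).
#' @export
kfold_cv <- function(pairs, targets, molecules, config = cpi_config(),
                     k = 5L, seed = 1L, ...) {
  pairs <- check_pairs(pairs)
  tids <- unique(pairs$target_id)
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  if (length(tids) < k)
    stop("fewer targets (", length(tids), ") than folds (", k, ")",
         call. = FALSE)
  folds <- with_seed(seed, {
    split(sample(tids), rep_len(seq_len(k), length(tids)))
  })
  fold_auc <- numeric(k)
  for (f in seq_len(k)) {
    hold <- folds[[f]]
    tr <- pairs[!pairs$target_id %in% hold, , drop = FALSE]
    te <- pairs[pairs$target_id %in% hold, , drop = FALSE]
    fit <- cpi_fit(tr, targets, molecules, config,
                   seed = seed + f, ...)
    fold_auc[f] <- roc_auc(predict(fit, te), te$label)
  }
  structure(list(fold_auc = fold_auc, mean_auc = mean(fold_auc),
                 folds = folds, k = k, seed = seed),
            class = "cpi_cv")
}

#' @export
print.cpi_cv <- function(x, ...) {
  cat(sprintf("%d-fold target-disjoint cross-validation\n", x$k))
  cat("  fold AUC:", paste(sprintf("%.3f", x$fold_auc), collapse = " "),
      "\n")
  cat(sprintf("  mean AUC: %.4f\n", x$mean_auc))
  invisible(x)
}

#' Positive-sample bookkeeping of the published screening benchmark
#'
#' The bundled per-target positive (active) counts of the 91-target
#' virtual-screening benchmark split used to size datasets: 68
#' training targets and 23 test targets. At a 1:1 active:decoy ratio
#' each target contributes twice its positive count in sample pairs.
#'
#' @param split `"train"`, `"test"` or `"both"`.
#' @return Data frame with `target_id` and `positives`.
#' @examples
#' sum(dude_positive_counts("train")$positives)   # 14515
#' @export
dude_positive_counts <- function(split = c("train", "test", "both")) {
  split <- match.arg(split)
  rd <- function(s) utils::read.delim(
    system.file("extdata", paste0("dude_", s, "_positives.tsv"),
                package = "cpiconv"), stringsAsFactors = FALSE)
  switch(split, train = rd("train"), test = rd("test"),
         both = rbind(cbind(rd("train"), split = "train"),
                      cbind(rd("test"), split = "test")))
}

#' Expected pair counts at a given active:decoy ratio
#'
#' From per-target positive counts, the number of sample pairs a fully
#' supplied assembly produces: `(ratio + 1) * sum(positives)`.
#'
#' @param counts data frame from [dude_positive_counts()] (or any with
#'   a `positives` column).
#' @param ratio decoys per active.
#' @return Integer pair count.
#' @examples
#' pair_count(dude_positive_counts("train"))   # 29030
#' @export
pair_count <- function(counts, ratio = 1L) {
  as.integer((ratio + 1L) * sum(counts$positives))
}
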