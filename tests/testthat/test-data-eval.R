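test_that("roc_auc matches hand values and rejects single-class input", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(rep(0.4, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_equal(roc_auc(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0)), 0.75)
  expect_error(roc_auc(c(0.1, 0.2), c(1, 1)), "both classes")
})

test_that("roc_auc equals brute-force concordance counting", {
  set.seed(16)
  for (rep in 1:50) {
    n <- sample(4:50, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    # mix continuous scores with ties
    s <- sample(round(runif(n), sample(c(1, 2, 6), 1)))
    expect_equal(roc_auc(s, y), oracle_auc(s, y), tolerance = 1e-12)
  }
})

test_that("roc_auc is invariant under strictly monotone transforms", {
  set.seed(17)
  s <- runif(30); y <- c(0, 1, rbinom(28, 1, 0.4))
  a <- roc_auc(s, y)
  expect_equal(roc_auc(qlogis(s), y), a)
  expect_equal(roc_auc(s^3 + 2 * s, y), a)
  expect_equal(roc_auc(exp(5 * s), y), a)
})

test_that("roc_auc agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(18)
  for (rep in 1:10) {
    n <- sample(10:60, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- round(runif(n), 2)
    ref <- suppressMessages(as.numeric(pROC::auc(y, s,
                                                 direction = "<")))
    expect_equal(roc_auc(s, y), ref, tolerance = 1e-12)
  }
})

test_that("per-target AUC counts use strict inequalities", {
  pairs <- data.frame(
    target_id = rep(c("a", "b", "c"), each = 4),
    ligand_id = paste0("m", 1:12),
    label = rep(c(1, 1, 0, 0), 3))
  # a perfect, b random-ish, c single-class (made degenerate below)
  pairs$label[9:12] <- 0
  scores <- c(0.9, 0.8, 0.2, 0.1,   # a: AUC 1
              0.6, 0.2, 0.5, 0.4,   # b: AUC 0.5
              0.5, 0.5, 0.5, 0.5)   # c: excluded
  expect_warning(pt <- per_target_auc(pairs, scores), "single-class")
  expect_equal(unname(pt$auc["a"]), 1)
  expect_equal(unname(pt$auc["b"]), 0.5)
  expect_equal(pt$excluded, "c")
  expect_equal(unname(pt$counts), c(1L, 1L, 1L))
  # boundary: an AUC of exactly 0.9 is not "> 0.9"
  p2 <- data.frame(target_id = "t", ligand_id = paste0("m", 1:5),
                   label = c(1, 1, 0, 0, 0))
  # positives beat all but one tie: 5.5 of 6 concordant pairs
  sc <- c(0.9, 0.5, 0.5, 0.2, 0.1)
  expect_equal(roc_auc(sc, p2$label), 11 / 12, tolerance = 1e-12)
  # thresholds applied to an empty AUC list give zero counts
  p3 <- data.frame(target_id = "t", ligand_id = c("a", "b"),
                   label = c(1, 1))
  expect_warning(pt3 <- per_target_auc(p3, c(0.1, 0.2)))
  expect_equal(unname(pt3$counts), c(0L, 0L, 0L))
})

test_that("threshold counts are non-increasing across 0.7/0.8/0.9", {
  set.seed(19)
  for (rep in 1:10) {
    nt <- sample(3:8, 1)
    pairs <- do.call(rbind, lapply(seq_len(nt), function(t)
      data.frame(target_id = paste0("t", t),
                 ligand_id = paste0("t", t, "_m", 1:10),
                 label = rep(c(1, 0), 5))))
    scores <- runif(nrow(pairs))
    pt <- suppressWarnings(per_target_auc(pairs, scores))
    expect_true(all(diff(pt$counts) <= 0))
  }
})

test_that("best-F1 threshold scanning matches enumeration", {
  # perfectly separated scores reach F1 = 1
  bf <- best_f1_threshold(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(bf$f1, 1)
  expect_gt(bf$threshold, 0.2)
  expect_lte(bf$threshold, 0.8)
  bf2 <- best_f1_threshold(c(0.9, 0.6, 0.4), c(1, 1, 0))
  expect_equal(bf2$f1, 1)
  expect_equal(bf2$threshold, 0.6)
  # threshold 0 predicts everything positive
  y <- c(1, 0, 0, 1, 0)
  bf3 <- best_f1_threshold(rep(0.5, 5), y)
  expect_equal(bf3$recall, 1)
  expect_equal(bf3$precision, mean(y))
  expect_error(best_f1_threshold(c(0.1, 0.2), c(1, 1)), "both classes")
})

test_that("pair assembly respects the active:decoy ratio", {
  acts <- list(t1 = paste0("a", 1:3), t2 = "a9")
  decs <- list(t1 = paste0("d", 1:20), t2 = paste0("e", 1:20))
  p <- assemble_pairs(acts, decs, ratio = 1, seed = 4)
  expect_equal(nrow(p), 2 * 3 + 2 * 1)
  p5 <- assemble_pairs(acts["t2"], decs["t2"], ratio = 5, seed = 4)
  expect_equal(nrow(p5), 6)
  expect_equal(sum(p5$label), 1)
  # (k+1) x actives per fully supplied target, for several k
  for (k in 1:3) {
    pk <- assemble_pairs(acts, decs, ratio = k, seed = 9)
    for (t in names(acts)) {
      expect_equal(sum(pk$target_id == t),
                   (k + 1) * length(acts[[t]]))
    }
  }
  # reproducible under the same seed
  expect_identical(assemble_pairs(acts, decs, 2, seed = 11),
                   assemble_pairs(acts, decs, 2, seed = 11))
  # shortfalls and empty targets warn
  expect_warning(assemble_pairs(list(t = c("a1", "a2")),
                                list(t = "d1"), ratio = 3, seed = 1),
                 "only")
  expect_warning(assemble_pairs(list(t = character(0), u = "a"),
                                list(t = "d", u = c("d1", "d2")),
                                ratio = 1, seed = 1), "no actives")
})

test_that("target-disjoint splitting conserves pairs and rejects overlap", {
  pairs <- data.frame(target_id = rep(c("a", "b", "c"), each = 2),
                      ligand_id = paste0("m", 1:6),
                      label = rep(c(1, 0), 3))
  sp <- split_by_target(pairs, c("a", "b"), "c")
  expect_equal(nrow(sp$train) + nrow(sp$test), nrow(pairs))
  expect_length(intersect(sp$train$target_id, sp$test$target_id), 0)
  expect_error(split_by_target(pairs, c("a", "b"), c("b", "c")),
               "overlap")
  sp2 <- split_by_target(pairs, c("a", "b", "c"), character(0))
  expect_equal(nrow(sp2$train), nrow(pairs))
  expect_equal(nrow(sp2$test), 0)
})

test_that("cross-validation folds are target-disjoint and reproducible", {
  tg <- generate_targets(4, seed = 21)
  mols <- cpi_smiles_library()[1:6]
  pairs <- do.call(rbind, lapply(names(tg), function(t)
    data.frame(target_id = t, ligand_id = names(mols),
               label = rep(c(1, 0), 3))))
  cfg <- cpi_config("small", epochs = 0L)
  cv1 <- kfold_cv(pairs, tg, mols, cfg, k = 2, seed = 31,
                  verbose = FALSE)
  cv2 <- kfold_cv(pairs, tg, mols, cfg, k = 2, seed = 31,
                  verbose = FALSE)
  expect_identical(cv1$folds, cv2$folds)
  expect_identical(cv1$fold_auc, cv2$fold_auc)
  expect_equal(lengths(cv1$folds), c(`1` = 2L, `2` = 2L))
  expect_length(intersect(cv1$folds[[1]], cv1$folds[[2]]), 0)
  expect_equal(cv1$mean_auc, mean(cv1$fold_auc))
  expect_error(kfold_cv(pairs, tg, mols, cfg, k = 5, seed = 1),
               "fewer targets")
})
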