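test_that("conv3d handles degenerate kernels as expected", {
  cube <- array(rnorm(2 * 4^3), c(2, 4, 4, 4))
  k0 <- array(0, c(2, 2, 2, 2, 3))
  expect_true(all(conv3d(cube, k0) == 0))
  # 1x1x1 delta kernel on one channel is the identity
  one <- array(rnorm(5^3), c(1, 5, 5, 5))
  kd <- array(1, c(1, 1, 1, 1, 1))
  expect_equal(conv3d(one, kd), one, tolerance = 1e-12)
  kbig <- array(1, c(6, 6, 6, 2, 1))
  expect_error(conv3d(cube, kbig), "exceeds")
  kwrong <- array(1, c(2, 2, 2, 3, 1))
  expect_error(conv3d(cube, kwrong), "channels")
})

test_that("conv3d matches the six-nested-loop oracle on random cubes", {
  set.seed(12)
  worst <- 0
  for (rep in 1:30) {
    C <- sample(1:2, 1); n <- sample(3:5, 1)
    k <- sample(2:min(3, n), 1); Fk <- sample(1:2, 1)
    cube <- array(rnorm(C * n^3), c(C, n, n, n))
    kern <- array(rnorm(k^3 * C * Fk), c(k, k, k, C, Fk))
    b <- rnorm(Fk)
    err <- max(abs(conv3d(cube, kern, b) - oracle_conv3d(cube, kern, b)))
    worst <- max(worst, err)
  }
  expect_lt(worst, 1e-8)
})

test_that("non-cubic kernel extents agree with the oracle", {
  set.seed(13)
  cube <- array(rnorm(2 * 4 * 5 * 3), c(2, 4, 5, 3))
  kern <- array(rnorm(2 * 3 * 1 * 2 * 2), c(2, 3, 1, 2, 2))
  b <- rnorm(2)
  expect_lt(max(abs(conv3d(cube, kern, b) -
                      oracle_conv3d(cube, kern, b))), 1e-10)
})

test_that("fusion concatenates in site, sequence, molecule order", {
  expect_equal(fuse_features(1, 2, 3), c(1, 2, 3))
  expect_equal(length(fuse_features(rnorm(128), rnorm(96), rnorm(128))),
               352)
  expect_equal(fuse_features(1, 2, 3, ablate = "sequence"), c(1, 3))
  expect_equal(fuse_features(1, NULL, 3, ablate = "sequence"), c(1, 3))
  expect_error(fuse_features(1, NULL, 3), "missing sequence")
  expect_error(fuse_features(NULL, 2, 3), "missing site")
})

test_that("focal loss matches its formula and reductions", {
  # perfect prediction drives the loss to zero
  expect_lt(focal_loss(1 - 1e-9, 1, gamma = 2, P = 1, N = 1), 1e-6)
  # reference value: y=1, y'=0.5, gamma=2, P=N
  expect_equal(focal_loss(0.5, 1, gamma = 2, P = 1, N = 1),
               -0.5 * 0.25 * log(0.5), tolerance = 1e-12)
  expect_equal(focal_loss(0.5, 1, gamma = 2, P = 1, N = 1), 0.086643,
               tolerance = 1e-5)
  # gamma=0, P=N reduces to half the binary cross-entropy
  set.seed(14)
  p <- runif(40, 0.01, 0.99)
  y <- rbinom(40, 1, 0.5)
  ce <- -(y * log(p) + (1 - y) * log(1 - p))
  expect_lt(max(abs(focal_loss(p, y, gamma = 0, P = 3, N = 3,
                               reduce = FALSE) - ce / 2)), 1e-10)
  # non-negativity and monotonicity in y' for positives
  expect_true(all(focal_loss(p, y, gamma = 2, P = 5, N = 2,
                             reduce = FALSE) >= 0))
  pp <- sort(runif(30, 0.01, 0.99))
  lp <- focal_loss(pp, 1, gamma = 2, P = 2, N = 5, reduce = FALSE)
  expect_true(all(diff(lp) <= 1e-12))
  # class-balance coefficients sum to one
  P <- 7; N <- 3
  expect_equal(N / (P + N) + P / (P + N), 1)
  # clamping keeps the loss finite at the boundaries
  expect_true(is.finite(focal_loss(0, 1)))
  expect_true(is.finite(focal_loss(1, 0)))
})

test_that("the focal-loss gradient matches finite differences", {
  set.seed(15)
  for (rep in 1:20) {
    z <- rnorm(1); y <- rbinom(1, 1, 0.5)
    gamma <- sample(c(0, 1, 2), 1); P <- sample(1:5, 1); N <- sample(1:5, 1)
    p <- plogis(z)
    g <- cpiconv:::focal_loss_grad_logit(p, y, gamma, P, N)
    eps <- 1e-6
    num <- (focal_loss(plogis(z + eps), y, gamma, P, N) -
              focal_loss(plogis(z - eps), y, gamma, P, N)) / (2 * eps)
    expect_equal(g, num, tolerance = 1e-5)
  }
})

test_that("full-model gradients match finite differences", {
  cfg <- cpi_config(grid_edge = 12, seq_max_len = 30,
                    seq_embed_dim = 3, seq_filters = c(3L, 4L, 4L),
                    seq_kernel = 3L, site_channels = c(2L, 3L, 3L),
                    site_kernel = 2L, gcn_widths = c(6L, 6L, 6L),
                    head_hidden = 5L)
  geom <- cpiconv:::model_geometry(cfg)
  set.seed(42)
  params <- cpiconv:::init_params(cfg, geom)
  tg <- generate_targets(2, seed = 7)
  tc <- featurize_targets(tg, cfg)
  mc <- featurize_molecules(cpi_smiles_library()[c(1, 120)])
  tid <- c(names(tc)[1], names(tc)[2], names(tc)[1])
  mid <- c(names(mc)[1], names(mc)[2], names(mc)[2])
  y <- c(1, 0, 1)
  loss_fn <- function(pp) {
    fw <- cpiconv:::batch_forward(pp, cfg, tc, mc, tid, mid)
    mean(focal_loss(fw$p, y, 2, 2, 1, reduce = FALSE))
  }
  fw <- cpiconv:::batch_forward(params, cfg, tc, mc, tid, mid,
                                need_cache = TRUE)
  dz <- cpiconv:::focal_loss_grad_logit(fw$p, y, 2, 2, 1)
  grads <- cpiconv:::batch_backward(fw, dz, params, cfg, tid, mid)
  eps <- 1e-6
  set.seed(1)
  for (grp in c("site", "seq", "mol", "head")) {
    for (nm in names(params[[grp]])) {
      v <- params[[grp]][[nm]]
      for (i in sample(length(v), min(3, length(v)))) {
        p2 <- params; p2[[grp]][[nm]][i] <- p2[[grp]][[nm]][i] + eps
        p3 <- params; p3[[grp]][[nm]][i] <- p3[[grp]][[nm]][i] - eps
        num <- (loss_fn(p2) - loss_fn(p3)) / (2 * eps)
        an <- grads[[grp]][[nm]][i]
        expect_lt(abs(num - an) / max(1e-6, abs(num) + abs(an)), 1e-4)
      }
    }
  }
})

test_that("prediction is deterministic, bounded, and 0.5 for a zero head", {
  cfg <- cpi_config("small", epochs = 0L)
  tg <- generate_targets(2, seed = 3)
  mols <- cpi_smiles_library()[1:4]
  pairs <- data.frame(target_id = rep(names(tg), 2),
                      ligand_id = names(mols), label = c(1, 0, 1, 0))
  fit <- cpi_fit(pairs, tg, mols, cfg, seed = 2, verbose = FALSE)
  p1 <- predict(fit, pairs)
  p2 <- predict(fit, pairs)
  expect_identical(p1, p2)
  expect_true(all(p1 > 0 & p1 < 1))
  fit0 <- fit
  fit0$params$head$Wh[] <- 0
  fit0$params$head$bh[] <- 0
  fit0$params$head$wo[] <- 0
  fit0$params$head$bo <- 0
  expect_equal(predict(fit0, pairs), rep(0.5, 4))
})
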