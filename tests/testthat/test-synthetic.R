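test_that("target generation is deterministic and well-formed", {
  t1 <- generate_targets(10, seed = 5)
  t2 <- generate_targets(10, seed = 5)
  expect_identical(t1, t2)
  expect_length(unique(names(t1)), 10)
  expect_length(generate_targets(0, seed = 5), 0)
  for (t in t1) {
    expect_true(nrow(t$site) >= 30 && nrow(t$site) <= 84)
    expect_true(all(is.finite(as.matrix(t$site[, c("x", "y", "z")]))))
    expect_true(nchar(t$sequence) >= 50 && nchar(t$sequence) <= 1200)
    # channel flags come from the typing rules: metals carry only
    # metal + excluded volume, organics never carry the metal flag
    m <- t$site$metal == 1
    expect_true(all(t$site$excluded == 1))
    if (any(m)) {
      expect_true(all(t$site$hydrophobic[m] == 0))
      expect_true(all(t$site$aromatic[m] == 0))
    }
    expect_true(all(t$site$metal[t$site$element %in%
                                   c("C", "N", "O")] == 0))
  }
  # a prefix of a larger batch equals the smaller batch (per-target
  # seeding)
  t3 <- generate_targets(3, seed = 5)
  expect_identical(t1[1:3], t3[1:3])
  # both site classes appear in any contiguous block
  metal <- vapply(t1, `[[`, TRUE, "metal")
  expect_true(any(metal[1:2]) && !all(metal[1:2]))
})

test_that("noise-free pair labels follow the planted rule exactly", {
  tg <- generate_targets(4, seed = 6)
  rule <- planted_rule(noise = 0)
  pr <- generate_pairs(tg, molecules_per_target = 20, ratio = 1,
                       rule = rule, seed = 7)
  expect_equal(nrow(pr$pairs), 4 * 20)
  graphs <- pr$graphs
  for (i in seq_len(nrow(pr$pairs))) {
    t <- tg[[pr$pairs$target_id[i]]]
    g <- graphs[[pr$pairs$ligand_id[i]]]
    want <- as.integer(any(t$site$metal == 1) &&
                         any(g$atoms$element == "N"))
    expect_equal(pr$pairs$label[i], want)
  }
  # ratio 1 with 10 predicate-positive molecules per target: 20 pairs
  expect_true(all(table(pr$pairs$target_id) == 20))
})

test_that("label noise flips the expected fraction", {
  tg <- generate_targets(13, seed = 8)
  p0 <- generate_pairs(tg, molecules_per_target = 80, ratio = 1,
                       rule = planted_rule(noise = 0), seed = 9)
  p1 <- generate_pairs(tg, molecules_per_target = 80, ratio = 1,
                       rule = planted_rule(noise = 0.1), seed = 9)
  n <- nrow(p0$pairs)
  expect_gte(n, 1000)
  flipped <- mean(p0$pairs$label != p1$pairs$label)
  se <- sqrt(0.1 * 0.9 / n)
  expect_lt(abs(flipped - 0.1), 3 * se)
})

test_that("an over-demanding ratio names the library shortfall", {
  tg <- generate_targets(1, seed = 2)
  expect_error(
    generate_pairs(tg, molecules_per_target = 600, ratio = 5,
                   rule = planted_rule(), seed = 1),
    "library exhausted")
})

test_that("dataset writing round-trips and regenerates byte-identically", {
  tg <- generate_targets(3, seed = 10)
  pr <- generate_pairs(tg, molecules_per_target = 10, ratio = 1,
                       rule = planted_rule(), seed = 11)
  d1 <- file.path(tempdir(), "synth1")
  d2 <- file.path(tempdir(), "synth2")
  unlink(c(d1, d2), recursive = TRUE)
  write_synthetic_dataset(tg, pr, d1)
  back <- read_synthetic_dataset(d1)
  expect_equal(back$pairs, pr$pairs)
  expect_equal(unname(back$molecules), unname(pr$molecules))
  expect_equal(names(back$targets), names(tg))
  expect_equal(back$targets[[1]]$sequence, tg[[1]]$sequence)
  expect_equal(back$targets[[2]]$site$x, tg[[2]]$site$x)
  # regeneration from the manifest parameters is byte-identical
  man <- back$manifest
  tg2 <- generate_targets(man$targets$n, seed = man$targets$seed)
  pr2 <- generate_pairs(tg2, man$pairs$molecules_per_target,
                        man$pairs$ratio,
                        planted_rule(man$pairs$rule$site_rule,
                                     man$pairs$rule$mol_rule,
                                     man$pairs$rule$noise),
                        seed = man$pairs$seed)
  write_synthetic_dataset(tg2, pr2, d2)
  f1 <- sort(list.files(d1))
  expect_identical(f1, sort(list.files(d2)))
  for (f in f1)
    expect_identical(readLines(file.path(d1, f), warn = FALSE),
                     readLines(file.path(d2, f), warn = FALSE))
})

test_that("the bundled molecule library parses and spans both pools", {
  lib <- cpi_smiles_library()
  expect_gte(length(lib), 200)
  graphs <- featurize_molecules(lib)   # errors on unparseable input
  expect_length(graphs, length(lib))
  has_n <- vapply(graphs, function(g) any(g$atoms$element == "N"), TRUE)
  expect_gte(sum(has_n), 60)
  expect_gte(sum(!has_n), 60)
})
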