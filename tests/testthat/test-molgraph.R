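test_that("atom featurization builds the five one-hot blocks", {
  # methane carbon: degree 0, 4 Hs, non-aromatic
  f <- featurize_atom("C", degree = 0, n_h = 4, n_implicit_h = 4)
  expect_length(f, 73)
  expect_equal(sum(f), 3 + 1 - 1 + 1)   # 4 ones
  expect_equal(f[1], 1)                 # C is the first atom type
  expect_equal(f[44 + 1], 1)            # degree 0
  expect_equal(f[44 + 6 + 5], 1)        # 4 Hs
  expect_equal(f[44 + 6 + 11 + 5], 1)   # 4 implicit Hs
  expect_equal(f[73], 0)
  # aromatic flag is the last position
  fb <- featurize_atom("C", 2, 1, 1, aromatic = TRUE)
  expect_equal(fb[73], 1)
  # unknown element maps to the catch-all X slot (position 44)
  fx <- featurize_atom("At", 1, 0, 0)
  expect_equal(fx[44], 1)
  expect_equal(sum(fx[1:43]), 0)
  # clamping of out-of-range buckets
  expect_warning(fc <- featurize_atom("C", degree = 7, n_h = 0,
                                      n_implicit_h = 0), "clamped")
  expect_equal(fc[44 + 6], 1)
})

test_that("block-wise one-hot structure holds across library molecules", {
  set.seed(8)
  lib <- cpi_smiles_library()
  graphs <- featurize_molecules(lib[sample(length(lib), 10)])
  for (g in graphs) {
    X <- g$X
    expect_equal(ncol(X), 73)
    expect_true(all(rowSums(X[, 1:44, drop = FALSE]) == 1))
    expect_true(all(rowSums(X[, 45:50, drop = FALSE]) == 1))
    expect_true(all(rowSums(X[, 51:61, drop = FALSE]) == 1))
    expect_true(all(rowSums(X[, 62:72, drop = FALSE]) == 1))
    expect_true(all(X %in% c(0, 1)))
  }
})

test_that("molecular graphs have the expected structure", {
  m <- mol_graph("C")
  expect_equal(m$n, 1)
  expect_equal(m$A, matrix(0, 1, 1))
  expect_equal(m$A_tilde, matrix(1, 1, 1))
  expect_equal(m$deg, 1)
  e <- mol_graph("CC")
  expect_equal(e$A, matrix(c(0, 1, 1, 0), 2))
  expect_equal(e$deg, c(2, 2))
  b <- mol_graph("c1ccccc1")
  expect_equal(b$n, 6)
  expect_true(all(rowSums(b$A) == 2))
  expect_true(all(b$deg == 3))
  expect_true(all(b$atoms$aromatic))
  # hydrogens are implicit: benzene carbons carry one H each
  expect_true(all(b$atoms$n_h == 1))
  # adjacency invariants
  expect_equal(b$A, t(b$A))
  expect_true(all(diag(b$A) == 0))
  expect_error(mol_graph("not_a_smiles((("), "unparseable|failed")
})

test_that("the normalized operator of a regular graph has rows summing to 1", {
  b <- mol_graph("c1ccccc1")
  expect_equal(rowSums(b$S), rep(1, 6), tolerance = 1e-12)
  # exactly three entries of 1/3 per row
  for (i in 1:6)
    expect_equal(sort(b$S[i, b$S[i, ] > 0]), rep(1 / 3, 3),
                 tolerance = 1e-12)
})

test_that("gcn_layer matches hand calculations and the dense oracle", {
  # edgeless single node with identity weights is the identity
  m <- mol_graph("C")
  H <- matrix(rnorm(73), 1)
  expect_equal(gcn_layer(H, m, diag(73)), H, ignore_attr = TRUE)
  # two-node path: normalized operator is [[.5,.5],[.5,.5]]
  e <- mol_graph("CC")
  expect_equal(e$S, matrix(0.5, 2, 2))
  out <- gcn_layer(matrix(c(1, 3), 2), e, matrix(1))
  expect_equal(as.vector(out), c(2, 2))
  # random graphs against the dense brute-force computation
  set.seed(9)
  for (rep in 1:30) {
    n <- sample(2:6, 1)
    A <- matrix(0, n, n)
    for (i in seq_len(n - 1)) {
      j <- sample(setdiff(seq_len(n), i), 1)
      A[i, j] <- A[j, i] <- 1
    }
    g <- structure(list(n = n, A = A, A_tilde = A + diag(n),
                        deg = rowSums(A + diag(n)),
                        S = (A + diag(n)) *
                          tcrossprod(1 / sqrt(rowSums(A + diag(n))))),
                   class = "mol_graph")
    H <- matrix(rnorm(n * 4), n, 4)
    W <- matrix(rnorm(4 * 3), 4, 3)
    expect_lt(max(abs(gcn_layer(H, g, W) - oracle_gcn(A, H, W))), 1e-10)
  }
})

test_that("gcn_layer is equivariant and readout invariant to node order", {
  set.seed(10)
  g <- mol_graph("CCO")
  H <- matrix(rnorm(3 * 5), 3, 5)
  W <- matrix(rnorm(5 * 4), 5, 4)
  base <- gcn_layer(H, g, W)
  for (rep in 1:5) {
    p <- sample(3)
    gp <- structure(list(n = 3, A = g$A[p, p],
                         A_tilde = g$A_tilde[p, p],
                         deg = g$deg[p], S = g$S[p, p]),
                    class = "mol_graph")
    out <- gcn_layer(H[p, , drop = FALSE], gp, W)
    expect_equal(out, base[p, , drop = FALSE], tolerance = 1e-12)
    expect_equal(mol_readout(out), mol_readout(base), tolerance = 1e-12)
  }
})

test_that("readout takes elementwise maxima over nodes", {
  expect_equal(mol_readout(matrix(c(1, -2), 1)), c(1, -2))
  H <- rbind(c(1, -2), c(0, 5))
  expect_equal(mol_readout(H), c(1, 5))
  expect_equal(mol_readout(rbind(H, H)), c(1, 5))
  expect_error(mol_readout(matrix(numeric(0), 0, 2)), "empty")
})

test_that("SMILES list files round-trip", {
  smi <- c(a = "CCO", b = "c1ccccc1")
  tf <- tempfile(fileext = ".smi")
  write_smiles_file(smi, tf)
  expect_equal(read_smiles_file(tf), smi)
  writeLines(c("onlyonefield"), tf)
  expect_error(read_smiles_file(tf), "malformed")
})
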