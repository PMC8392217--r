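test_that("occupancy follows the soft-sphere formula and its limits", {
  expect_equal(occupancy(1.7, 1.7), 1 - exp(-1), tolerance = 1e-12)
  expect_equal(occupancy(0, 1.5), 1)
  expect_equal(occupancy(2 * 1.3, 1.3), 1 - exp(-2^(-12)),
               tolerance = 1e-12)
  expect_equal(occupancy(2 * 1.3, 1.3), 2.4411e-4, tolerance = 1e-3)
  expect_error(occupancy(-1, 1.5), "non-negative")
  expect_error(occupancy(1, 0), "positive")
  expect_error(occupancy(1, -2), "positive")
})

test_that("occupancy is monotone decreasing in r and bounded in [0,1]", {
  set.seed(1)
  for (rep in 1:20) {
    rvdw <- runif(1, 0.5, 3)
    r <- sort(runif(50, 0, 12))
    o <- occupancy(r, rvdw)
    expect_true(all(o >= 0 & o <= 1))
    expect_true(all(diff(o) <= 1e-15))
  }
})

test_that("site_center is the arithmetic centroid", {
  expect_equal(site_center(matrix(c(1, 2, 3), 1)), c(1, 2, 3))
  expect_equal(site_center(rbind(c(0, 0, 0), c(2, 0, 0))), c(1, 0, 0))
  pts <- rbind(c(1, 2, 3), c(-1, 0, 5), c(4, 4, 4), c(0, -2, 0))
  expect_equal(site_center(pts), colSums(pts) / 4)
  expect_error(site_center(matrix(numeric(0), 0, 3)), "empty")
})

test_that("channel typing follows the documented rule table", {
  zn <- assign_channels("Zn")
  expect_true(zn["metal"] && zn["excluded"])
  expect_equal(sum(zn), 2)
  # metals never carry hydrophobic or aromatic flags
  for (m in c("Zn", "Fe", "Mg", "Ca", "Cu"))
    expect_false(any(assign_channels(m)[c("hydrophobic", "aromatic")]))
  cc <- assign_channels("C", polar_neighbors = 0)
  expect_true(cc["hydrophobic"] && cc["excluded"])
  expect_equal(sum(cc), 2)
  # backbone-carbonyl-type oxygen: acceptor + excluded volume
  o <- assign_channels("O", bonded_h = 0)
  expect_true(o["acceptor"] && o["excluded"])
  expect_false(o["donor"])
  # amide-type N with hydrogens: donor
  nd <- assign_channels("N", bonded_h = 1, lone_pair = FALSE)
  expect_true(nd["donor"])
  expect_false(nd["acceptor"])
  expect_warning(unk <- assign_channels("Qq"), "unrecognized")
  expect_equal(unname(which(unk)), 8L)
})

test_that("an empty atom list voxelizes to an all-zero 8x30x30x30 grid", {
  g <- build_site_grid(data.frame(element = character(0),
                                  x = numeric(0), y = numeric(0),
                                  z = numeric(0)))
  expect_equal(dim(g), c(8, 30, 30, 30))
  expect_true(all(g == 0))
})

test_that("a metal atom at a voxel center paints the metal channel", {
  # voxel centers sit at half-integer offsets; (0.5, 0.5, 0.5) is one
  at <- data.frame(element = "Zn", x = 0.5, y = 0.5, z = 0.5)
  g <- build_site_grid(at, center = c(0, 0, 0))
  expect_equal(max(g["metal", , , ]), 1)
  expect_true(all(g[c(1:6), , , ] == 0))
  # every other voxel of the metal channel equals the occupancy at its
  # center distance (checked against an independent brute-force pass)
  or <- oracle_grid(cbind(at, vdw = vdw_radius("Zn"),
                          as.data.frame(t(assign_channels("Zn") + 0L))),
                    center = c(0, 0, 0))
  expect_lt(max(abs(g - or)), 1e-10)
})

test_that("grids match the naive triple-loop oracle on random atoms", {
  set.seed(7)
  for (rep in 1:3) {
    n_at <- sample(3:8, 1)
    els <- sample(c("C", "O", "N", "Zn", "S"), n_at, replace = TRUE)
    at <- data.frame(element = els,
                     x = runif(n_at, -10, 10),
                     y = runif(n_at, -10, 10),
                     z = runif(n_at, -10, 10))
    at$vdw <- vdw_radius(at$element)
    fl <- t(vapply(at$element, function(e)
      suppressWarnings(assign_channels(e)), logical(8)))
    at <- cbind(at, as.data.frame(fl + 0L))
    g <- build_site_grid(at, center = c(0, 0, 0), edge = 8)
    or <- oracle_grid(at, center = c(0, 0, 0), edge = 8)
    expect_lt(max(abs(g - or)), 1e-10)
  }
})

test_that("grid building is idempotent, translation- and order-invariant", {
  at <- fixture_site_atoms()
  g1 <- build_site_grid(at, center = c(0, 0, 0))
  # duplicated atoms change nothing (max aggregation)
  g2 <- build_site_grid(rbind(at, at), center = c(0, 0, 0))
  expect_equal(g1, g2, tolerance = 1e-12, ignore_attr = TRUE)
  # translation of atoms and center together
  sh <- c(3.2, -1.7, 0.4)
  at3 <- at; at3$x <- at3$x + sh[1]; at3$y <- at3$y + sh[2]
  at3$z <- at3$z + sh[3]
  g3 <- build_site_grid(at3, center = sh)
  expect_lt(max(abs(g1 - g3)), 1e-10)
  # permutation of atom order
  g4 <- build_site_grid(at[rev(seq_len(nrow(at))), ],
                        center = c(0, 0, 0))
  expect_equal(g1, g4, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("atoms outside the box still contribute to voxels inside", {
  # atom 1 A outside the 8 A box face, vdw reach crosses the boundary
  at <- data.frame(element = "C", x = 5, y = 0, z = 0)
  at$vdw <- 1.7
  fl <- as.data.frame(t(assign_channels("C") + 0L))
  g <- build_site_grid(cbind(at, fl), center = c(0, 0, 0), edge = 8)
  expect_gt(max(g["hydrophobic", , , ]), 0)
})

test_that("site-atom tables and grid containers round-trip", {
  at <- fixture_site_atoms()
  tf <- tempfile(fileext = ".tsv")
  write_site_atoms(at, tf)
  back <- read_site_atoms(tf)
  expect_equal(back$element, at$element)
  expect_equal(back$x, at$x)
  g1 <- build_site_grid(at, center = c(0, 0, 0))
  g2 <- build_site_grid(at, center = c(1, 1, 1))
  bf <- tempfile(fileext = ".bin")
  write_grids(list(a = g1, b = g2), bf)
  back2 <- read_grids(bf)
  expect_equal(names(back2), c("a", "b"))
  expect_equal(as.vector(back2$a), as.vector(g1))
  expect_equal(as.vector(back2$b), as.vector(g2))
  expect_error(read_site_atoms({
    t2 <- tempfile(); writeLines("a\tb\n1\t2", t2); t2
  }), "lacks column")
})

test_that("PDB site extraction types protein atoms and metals", {
  pdb <- c(
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00           C",
    "ATOM      3  C   ALA A   1      10.729   6.768  -4.123  1.00  0.00           C",
    "ATOM      4  O   ALA A   1       9.581   6.342  -3.935  1.00  0.00           O",
    "ATOM      5  CB  ALA A   1      11.814   4.620  -4.712  1.00  0.00           C",
    "ATOM      6  CG  PHE A   2       8.000   2.000   1.000  1.00  0.00           C",
    "ATOM      7  OD1 ASP A   3       7.000   1.000   0.000  1.00  0.00           O",
    "HETATM    8 ZN    ZN A 101       5.000   5.000   5.000  1.00  0.00          ZN",
    "END")
  tf <- tempfile(fileext = ".pdb")
  writeLines(pdb, tf)
  at <- read_site_pdb(tf)
  expect_equal(nrow(at), 8)
  expect_true(at$metal[at$element == "Zn"] == 1)
  # backbone N is a donor, backbone O an acceptor
  expect_equal(at$donor[1], 1L)
  expect_equal(at$acceptor[4], 1L)
  # PHE ring carbon is aromatic; ASP carboxylate O negative ionizable
  expect_equal(at$aromatic[6], 1L)
  expect_equal(at$negative[7], 1L)
  # all heavy atoms carry excluded volume
  expect_true(all(at$excluded == 1))
  # residue selection restricts rows
  expect_equal(nrow(read_site_pdb(tf, resno = 1)), 5)
})
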