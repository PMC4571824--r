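# Structure reading, coarse graining, native topology and scaffolds.

test_that("read_pdb returns the literal records of a hand-written file", {
  path <- system.file("extdata", "toy3.pdb", package = "tunnelfold")
  at <- read_pdb(path)
  expect_s3_class(at, "atomset")
  expect_equal(nrow(at), 3)
  expect_equal(at$elety, c("N", "CA", "C"))
  expect_equal(at$x, c(0, 1.458, 2.010))
  expect_equal(at$y, c(0, 0, 1.420))
})

test_that("read_pdb errors: missing file, empty selection, malformed line", {
  expect_error(read_pdb(tempfile()), "not found")
  path <- system.file("extdata", "toy3.pdb", package = "tunnelfold")
  expect_error(read_pdb(path, chain = "Z"), "empty selection")
  bad <- write_pdb_fixture(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000",
    "ATOM      2  CA  ALA A   2       1.0bad   0.000   0.000  1.00  0.00",
    "END"))
  expect_error(read_pdb(bad), "line 2")
})

test_that("first altloc wins for duplicated atoms", {
  path <- write_pdb_fixture(c(
    "ATOM      1  CA AALA A   1       1.000   0.000   0.000  0.50  0.00           C",
    "ATOM      2  CA BALA A   1       9.000   0.000   0.000  0.50  0.00           C",
    "END"))
  at <- read_pdb(path)
  expect_equal(nrow(at), 1)
  expect_equal(at$x, 1.0)
})

test_that("coarse graining places backbone and side-chain beads", {
  # Gly-Gly: two-bead mode still yields only backbone beads
  gly2 <- write_pdb_fixture(c(
    "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  GLY A   2       3.800   0.000   0.000  1.00  0.00           C",
    "END"))
  cg <- coarse_grain(read_pdb(gly2), mode = "two_bead")
  expect_equal(nrow(cg$beads), 2)
  expect_true(all(cg$beads$role == "backbone"))

  # Ala with one side-chain heavy atom: centroid is that atom
  ala <- write_pdb_fixture(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CB  ALA A   1       1.500   0.000   0.000  1.00  0.00           C",
    "END"))
  cg <- coarse_grain(read_pdb(ala), mode = "two_bead")
  expect_equal(nrow(cg$beads), 2)
  expect_equal(cg$xyz[cg$beads$role == "sidechain", ], c(1.5, 0, 0))

  # centroid arithmetic on a residue with several side-chain atoms
  multi <- write_pdb_fixture(c(
    "ATOM      1  CA  LEU A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CB  LEU A   1       1.000   1.000   0.000  1.00  0.00           C",
    "ATOM      3  CG  LEU A   1       3.000   1.000   0.000  1.00  0.00           C",
    "ATOM      4  CD1 LEU A   1       2.000   4.000   3.000  1.00  0.00           C",
    "END"))
  cg <- coarse_grain(read_pdb(multi), mode = "two_bead")
  expect_equal(cg$xyz[2, ], c(2, 2, 1))  # hand-computed centroid

  # a residue with no CA is an error naming the residue
  noca <- write_pdb_fixture(c(
    "ATOM      1  CB  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "END"))
  expect_error(coarse_grain(read_pdb(noca)), "ALA1")
})

test_that("native topology has the right bonded terms and contact rules", {
  xyz3 <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(3.8, 3.8, 0))
  topo <- build_native_topology(tiny_chain(xyz3))
  expect_equal(nrow(topo$bonds), 2)
  expect_equal(nrow(topo$angles), 1)
  expect_equal(nrow(topo$dihedrals), 0)
  expect_equal(nrow(topo$contacts), 0)
  expect_equal(topo$bonds$r0, c(3.8, 3.8))
  expect_equal(topo$angles$theta0, pi / 2, tolerance = 1e-9)

  # 4 collinear beads 3.8 A apart: the only |i-j| >= 3 pair is 11.4 A out
  xyz4 <- cbind(seq(0, by = 3.8, length.out = 4), 0, 0)
  topo4 <- build_native_topology(tiny_chain(xyz4), contact_cutoff = 8)
  expect_equal(nrow(topo4$contacts), 0)

  expect_error(build_native_topology(tiny_chain(xyz3[1, , drop = FALSE])),
               "at least 2")
})

test_that("toy-domain contact list equals a brute-force all-pairs scan", {
  dom <- make_toy_domain(seed = 3)
  topo <- build_native_topology(dom, contact_cutoff = 8)
  # independent O(n^2) oracle
  D <- as.matrix(dist(dom$xyz))
  expected <- which(upper.tri(D) & D < 8 &
                      abs(row(D) - col(D)) >= 3, arr.ind = TRUE)
  got <- as.matrix(topo$contacts[, c("i", "j")])
  dimnames(got) <- NULL
  o1 <- order(expected[, 1], expected[, 2])
  o2 <- order(got[, 1], got[, 2])
  expect_equal(got[o2, , drop = FALSE],
               unname(expected[o1, , drop = FALSE]))
  # contact invariants: stored once with i < j, never |i-j| < 3
  expect_true(all(topo$contacts$i < topo$contacts$j))
  expect_true(all(topo$contacts$j - topo$contacts$i >= 3))
  expect_equal(topo$contacts$sigma,
               D[cbind(topo$contacts$i, topo$contacts$j)])
})

test_that("coarse-bead PDB round trip preserves coordinates to 1e-3 A", {
  dom <- make_toy_domain()
  path <- tempfile(fileext = ".pdb")
  write_cg_pdb(dom, path)
  back <- coarse_grain(read_pdb(path))
  expect_equal(nrow(back$beads), nrow(dom$beads))
  expect_lt(max(abs(back$xyz - dom$xyz)), 1e-3)
})

test_that("build_scaffold filters by axis distance and resolves anchors", {
  set.seed(8)
  at <- data.frame(elety = "P", elesy = "P", resno = 1:10, resid = "U",
                   chain = "A", insert = "", x = runif(10, -8, 8),
                   y = runif(10, -8, 8), z = runif(10, -20, 0),
                   type = "ATOM")
  sc_all <- build_scaffold(at, anchor = c(0, 0, 0), exit = c(0, 0, -20),
                           keep_within = Inf)
  expect_equal(nrow(sc_all$xyz), 10)
  sc5 <- build_scaffold(at, anchor = c(0, 0, 0), exit = c(0, 0, -20),
                        keep_within = 5)
  # oracle: per-atom distance to the z axis
  keep <- sqrt(at$x^2 + at$y^2) <= 5
  expect_equal(nrow(sc5$xyz), sum(keep))
  expect_equal(unname(sc5$xyz[, 1]), at$x[keep])

  expect_error(build_scaffold(at, anchor = list(resno = 99), exit = c(0, 0, -1)),
               "no atom")
  expect_error(build_scaffold(at, anchor = list(elety = "P"), exit = c(0, 0, -1)),
               "ambiguous")
  sc1 <- build_scaffold(at, anchor = list(resno = 3), exit = c(0, 0, -20))
  expect_equal(sc1$anchor, c(at$x[3], at$y[3], at$z[3]))
})

test_that("scaffold coordinates are untouched by dynamics", {
  tun <- make_toy_tunnel(length = 60)
  before <- tun$xyz
  ch <- attach_linker(make_toy_domain(), 5)
  topo <- build_native_topology(ch)
  conf <- conformation(ch, topo, xyz = initial_tethered_xyz(ch, tun),
                       scaffold = tun, tether = TRUE)
  invisible(langevin_run(conf, 310, steps = 2000, seed = 1, n_save = 500))
  expect_identical(tun$xyz, before)
})
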