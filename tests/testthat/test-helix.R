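test_that("an untilted helix has its principal axis on the surface normal", {
  h <- make_ideal_helix(26, tilt = 0, azimuth = 135)
  ax <- helix_axis(h)
  expect_lt(max(abs(ax - c(0, 0, 1))), 1e-6)
})

test_that("a lying helix keeps all C-alpha atoms within one diameter in z", {
  h <- make_ideal_helix(26, tilt = 90, azimuth = 0, base_z = 3)
  ca <- h$atoms[h$atoms$atom == "CA", ]
  # one C-alpha diameter plus the sub-degree principal-axis alignment slack
  expect_lte(max(ca$z) - min(ca$z), 2 * helix_geometry()$radius + 0.1)
  expect_gte(min(h$atoms$z), 3 - 1e-9)
})

test_that("generated tilt is recovered by the axis estimator", {
  for (tilt in c(5, 20.9, 29.7, 37, 66)) {
    h <- make_ideal_helix(26, tilt = tilt, azimuth = 123)
    expect_equal(tilt_angle(helix_axis(h)), tilt, tolerance = 1e-6,
                 info = paste("tilt", tilt))
  }
})

test_that("recovered tilt is invariant under azimuth", {
  set.seed(42)
  azis <- stats::runif(100, 0, 360)
  tilts <- vapply(azis, function(a) {
    tilt_angle(helix_axis(make_ideal_helix(26, tilt = 37, azimuth = a)))
  }, numeric(1))
  expect_lt(max(abs(tilts - 37)), 0.5)
})

test_that("consecutive C-alpha distances are constant", {
  h <- make_ideal_helix(26, tilt = 28, azimuth = 77)
  ca <- as.matrix(h$atoms[h$atoms$atom == "CA", c("x", "y", "z")])
  d <- sqrt(rowSums((ca[-1, ] - ca[-nrow(ca), ])^2))
  expect_lt(max(d) - min(d), 1e-6)
})

test_that("helices below the estimator's minimum length are refused", {
  expect_error(make_ideal_helix(3), "n_residues must be >= 4")
})

test_that("the generated helix is exactly alpha-helical by dihedrals", {
  h <- make_ideal_helix(20)
  expect_equal(as.numeric(helicity_fraction(h)), 1.0)
})

test_that("coordinate jitter is reproducible and seed-controlled", {
  h1 <- make_ideal_helix(12, tilt = 10, jitter_sd = 0.1, seed = 7)
  h2 <- make_ideal_helix(12, tilt = 10, jitter_sd = 0.1, seed = 7)
  h3 <- make_ideal_helix(12, tilt = 10, jitter_sd = 0.1, seed = 8)
  expect_identical(h1$atoms, h2$atoms)
  expect_false(identical(h1$atoms, h3$atoms))
})

test_that("terminus_down controls which end faces the surface", {
  hN <- make_ideal_helix(26, tilt = 20, terminus_down = "N")
  hC <- make_ideal_helix(26, tilt = 20, terminus_down = "C")
  zN <- hN$atoms$z[hN$atoms$atom == "CA"]
  zC <- hC$atoms$z[hC$atoms$atom == "CA"]
  expect_lt(zN[1], zN[26])
  expect_gt(zC[1], zC[26])
})

test_that("dihedral-driven backbone builder honors its angles", {
  n <- 10
  ext <- build_backbone(rep(180, n), rep(180, n))
  expect_equal(as.numeric(helicity_fraction(ext)), 0)
  # consecutive C-alpha distance of a fully extended chain is ~3.8 A
  ca <- as.matrix(ext$atoms[ext$atoms$atom == "CA", c("x", "y", "z")])
  d <- sqrt(rowSums((ca[-1, ] - ca[-nrow(ca), ])^2))
  expect_true(all(d > 3.5 & d < 4.0))
})

test_that("PDB writing and reading round-trips coordinates", {
  h <- make_ideal_helix(15, tilt = 33, azimuth = 10,
                        sequence = substr(get_peptide("wild_type")$sequence,
                                          1, 15))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure_pdb(h, path)
  h2 <- read_structure_pdb(path)
  expect_equal(nrow(h2$atoms), nrow(h$atoms))
  for (cc in c("x", "y", "z")) {
    expect_lt(max(abs(h2$atoms[[cc]] - h$atoms[[cc]])), 1e-3 + 1e-9)
  }
  expect_identical(h2$atoms$resname, h$atoms$resname)
  expect_equal(tilt_angle(helix_axis(h2)), 33, tolerance = 0.01)
})

test_that("degenerate PDB inputs raise explicit errors", {
  empty <- withr::local_tempfile(fileext = ".pdb")
  writeLines("END", empty)
  expect_error(read_structure_pdb(empty))
  noca <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "END"), noca)
  expect_error(read_structure_pdb(noca), "no C-alpha")
})
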