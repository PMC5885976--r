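test_that("principal-axis and local-axes estimators agree", {
  h <- make_ideal_helix(26, tilt = 24, azimuth = 80)
  a1 <- helix_axis(h)
  a2 <- local_helix_axis(h)
  angle <- acos(min(abs(sum(a1 * a2)), 1)) * 180 / pi
  expect_lt(angle, 1)
})

test_that("tilt angles fold into [0, 90] degrees", {
  expect_equal(tilt_angle(c(0, 0, 1)), 0)
  expect_equal(tilt_angle(c(1, 0, 0)), 90)
  expect_equal(tilt_angle(c(0, 0, -1)), 0)
  expect_equal(tilt_angle(c(0, 1, -1)), 45, tolerance = 1e-10)
  expect_error(tilt_angle(c(0, 0, 0)), "zero vector")
})

test_that("tilt is invariant under z-rotations and axis negation", {
  set.seed(3)
  h <- make_ideal_helix(26, tilt = 52)
  ax <- helix_axis(h)
  for (i in 1:100) {
    a <- stats::runif(1, 0, 2 * pi)
    R <- rot_z_test(a)
    s <- sample(c(-1, 1), 1)
    expect_equal(tilt_angle(s * as.numeric(R %*% ax)), 52,
                 tolerance = 0.5)
  }
})

test_that("the axis estimator rejects degenerate and short inputs", {
  h <- make_ideal_helix(26)
  expect_error(helix_axis(h, residue_range = c(1, 3)), "at least 4")
  # points on a circle have two exactly equal leading variances
  ang <- seq(0, 2 * pi, length.out = 9)[-9]
  cloud <- structure_model(data.frame(
    atom = "CA", element = "C", resid = seq_along(ang), resname = "ALA",
    chain = "A", x = cos(ang), y = sin(ang), z = 0, het = FALSE))
  expect_error(helix_axis(cloud), "degenerate")
})

test_that("helicity is 1 for an ideal helix and 0 for an extended chain", {
  expect_equal(as.numeric(helicity_fraction(make_ideal_helix(26))), 1)
  ext <- build_backbone(rep(180, 12), rep(180, 12))
  expect_equal(as.numeric(helicity_fraction(ext)), 0)
})

test_that("partially unwound chains give an exact residue count", {
  n <- 26
  n_ext <- 6
  phi <- c(rep(-57, n - n_ext), rep(180, n_ext))
  psi <- c(rep(-47, n - n_ext), rep(180, n_ext))
  m <- build_backbone(phi, psi)
  h <- helicity_fraction(m)
  # termini (first and last residue) lack one dihedral each
  expect_identical(attr(h, "n_excluded"), 2L)
  n_assessed <- n - 2
  # helical residues: 2..(n - n_ext); residue n - n_ext keeps its own
  # (phi, psi) parameters, the extended block starts at n - n_ext + 1
  expect_equal(as.numeric(h), (n - n_ext - 1) / n_assessed)
})

test_that("helicity is invariant under rigid-body motion", {
  h <- make_ideal_helix(20, tilt = 35)
  a <- h$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")])
  R <- rot_z_test(1.1) %*% rot_y_test(0.4)
  xyz2 <- sweep(xyz %*% t(R), 2, c(5, -3, 12), `+`)
  a[, c("x", "y", "z")] <- xyz2
  h2 <- structure_model(a)
  expect_equal(as.numeric(helicity_fraction(h2)),
               as.numeric(helicity_fraction(h)), tolerance = 1e-9)
})

test_that("a standing helix with nine C-terminal residues low binds via C", {
  h <- make_ideal_helix(26, tilt = 20.9, terminus_down = "C",
                        sequence = get_peptide("wild_type")$sequence)
  a <- h$atoms
  minz <- vapply(1:26, function(r) min(a$z[a$resid == r]), numeric(1))
  srt <- sort(minz)
  cutoff <- (srt[9] + srt[10]) / 2
  con <- terminus_contacts(h, z_cutoff = cutoff)
  expect_identical(sum(con$contacts), 9L)
  expect_true(all(which(con$contacts) >= 18))  # the 9 C-terminal residues
  expect_identical(con$binding_terminus, "C")
})

test_that("contact classification covers none / both / N", {
  high <- make_ideal_helix(26, tilt = 20, base_z = 10)
  expect_identical(terminus_contacts(high, 4)$binding_terminus, "none")
  lying <- make_ideal_helix(26, tilt = 90, base_z = 2)
  con <- terminus_contacts(lying, 4)
  expect_identical(con$binding_terminus, "both")
  # the cylinder curls some residues' atoms above the cutoff, but both
  # halves are firmly in contact
  expect_gte(con$n_contact_n_half, 13 / 3)
  expect_gte(con$n_contact_c_half, 13 / 3)
  standN <- make_ideal_helix(26, tilt = 15, terminus_down = "N")
  expect_identical(terminus_contacts(standN, 5)$binding_terminus, "N")
})

test_that("contacts are monotone in the cutoff", {
  h <- make_ideal_helix(26, tilt = 40, terminus_down = "C")
  prev <- rep(FALSE, 26)
  for (zc in seq(1, 40, by = 2)) {
    cur <- terminus_contacts(h, zc)$contacts
    expect_true(all(cur[prev]))
    prev <- cur
  }
})

test_that("snapshot analysis composes tilt, helicity, contacts and pose", {
  wt <- get_peptide("wild_type")
  standing <- analyze_snapshot(make_ideal_helix(
    26, tilt = 20.9, terminus_down = "C", sequence = wt$sequence))
  expect_identical(standing$classification, "standing")
  expect_identical(standing$binding_terminus, "C")
  expect_equal(standing$tilt_deg, 20.9, tolerance = 0.05)
  expect_equal(standing$helicity_fraction, 1)

  lying <- analyze_snapshot(make_ideal_helix(
    26, tilt = 90, base_z = 2, sequence = get_peptide("mutant_B")$sequence))
  expect_identical(lying$classification, "lying")
})

test_that("snapshot series report circular-aware mean tilts", {
  dir <- withr::local_tempdir()
  tilts <- c(18, 21, 24)
  for (i in seq_along(tilts)) {
    write_structure_pdb(
      make_ideal_helix(26, tilt = tilts[i], azimuth = 100 * i),
      file.path(dir, sprintf("snap_%02d.pdb", i)))
  }
  ser <- analyze_snapshots(dir)
  expect_identical(ser$n, 3L)
  expect_equal(ser$tilt_mean_deg, mean(tilts), tolerance = 0.05)
  expect_equal(ser$tilt_first_deg, 18, tolerance = 0.05)
  expect_equal(ser$tilt_last_deg, 24, tolerance = 0.05)
  expect_equal(ser$tilt_sd_deg, stats::sd(tilts), tolerance = 0.05)
})

test_that("HETATM records are kept but excluded from the analysis", {
  h <- make_ideal_helix(10, tilt = 0, base_z = 5)
  a <- h$atoms
  surf <- data.frame(atom = "S", element = "S", resid = 999,
                     resname = "SUB", chain = "B",
                     x = 0, y = 0, z = 0, het = TRUE)
  h2 <- structure_model(rbind(a, surf))
  expect_equal(tilt_angle(helix_axis(h2)), 0, tolerance = 1e-6)
  con <- terminus_contacts(h2, 4)
  expect_length(con$contacts, 10)
})
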