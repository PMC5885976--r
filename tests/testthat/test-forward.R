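test_that("a one-residue helix reduces to the single-unit tensor", {
  p <- unit_tensor_params(dipole_tilt = 38, raman_ratio = 0.32)
  b <- helix_beta(1, p)
  d <- 38 * pi / 180
  R <- rot_y_test(d)
  alpha <- R %*% diag(c(0.32, 0.32, 1)) %*% t(R)
  mu <- as.numeric(R %*% c(0, 0, 1))
  expected <- outer(alpha, mu)
  expect_equal(Re(b$A), expected, tolerance = 1e-12)
  expect_equal(Re(b$E1plus), expected, tolerance = 1e-12)
})

test_that("E1 tensors match direct coherent summation over unit phases", {
  n <- 18  # five full turns at 100 deg/residue
  p <- unit_tensor_params()
  g100 <- helix_geometry(twist_per_residue = 100)
  b <- helix_beta(n, p, g100)
  d <- p$dipole_tilt * pi / 180
  # collective Raman and IR derivative sums of the m = +1 exciton branch
  Sa <- matrix(0 + 0i, 3, 3)
  Sm <- rep(0 + 0i, 3)
  for (k in 0:(n - 1)) {
    psik <- k * 100 * pi / 180
    R <- rot_z_test(psik) %*% rot_y_test(d)
    Sa <- Sa + (R %*% diag(c(p$raman_ratio, p$raman_ratio, 1)) %*% t(R)) *
      exp(-1i * psik)
    Sm <- Sm + as.numeric(R %*% c(0, 0, 1)) * exp(1i * psik)
  }
  acc <- outer(Sa, Sm) / n
  expect_equal(b$E1plus, acc, tolerance = 1e-12)
  expect_equal(b$E1minus, Conj(acc), tolerance = 1e-12)
  # for integer turns the E1 tensor is purely off-diagonal in c
  expect_lt(abs(b$E1plus[3, 3, 3]), 1e-10)
  expect_lt(abs(b$E1plus[1, 1, 3] + b$E1plus[2, 2, 3]), 1e-10)
})

test_that("the A mode is axially symmetric for integer turns", {
  b <- helix_beta(18, geometry = helix_geometry(twist_per_residue = 100))
  expect_equal(Re(b$A[1, 1, 3]), Re(b$A[2, 2, 3]), tolerance = 1e-10)
  # rotating the whole tensor about the helix axis changes nothing axial
  for (az in c(30, 161)) {
    rot <- apply_rot3(b$A, rot_z_test(az * pi / 180))
    expect_equal(abs(rot[3, 3, 3]), abs(b$A[3, 3, 3]), tolerance = 1e-10)
    expect_equal(abs(rot[1, 1, 3] + rot[2, 2, 3]),
                 abs(b$A[1, 1, 3] + b$A[2, 2, 3]), tolerance = 1e-10)
  }
})

test_that("A-mode hyperpolarizability scales linearly with length", {
  g100 <- helix_geometry(twist_per_residue = 100)
  b18 <- helix_beta(18, geometry = g100)
  b36 <- helix_beta(36, geometry = g100)
  expect_equal(b36$A, 2 * b18$A, tolerance = 1e-10)
})

test_that("every chi component vanishes for a lying film", {
  chi <- chi_lab(helix_beta(26), theta = 90)
  expect_lt(max(abs(unlist(chi$total))), 1e-12)
})

test_that("every chi component vanishes for an isotropic film", {
  chi <- chi_lab(helix_beta(26), theta = 0, distribution = "isotropic")
  expect_lt(max(abs(unlist(chi$total))), 1e-10)
})

test_that("closed-form averaging matches the brute-force Euler oracle", {
  b <- helix_beta(26)
  chi <- chi_lab(b, theta = 37)
  oracle <- chi_brute_total(b, 37)
  for (cmp in c("xxz", "xzx", "zxx", "zzz")) {
    expect_equal(chi$total[[cmp]], oracle[[cmp]],
                 tolerance = 1e-6, info = cmp)
  }
})

test_that("oracle equivalence holds across random parameter sets", {
  set.seed(7)
  for (i in 1:20) {
    theta <- stats::runif(1, 1, 89)
    delta <- stats::runif(1, 10, 80)
    r <- stats::runif(1, -0.5, 1.5)
    b <- helix_beta(26, unit_tensor_params(delta, r))
    chi <- chi_lab(b, theta)
    oracle <- chi_brute_total(b, theta, n_grid = 180)
    scale <- max(abs(unlist(oracle)), 1e-12)
    for (cmp in c("xxz", "xzx", "zxx", "zzz")) {
      expect_lt(abs(chi$total[[cmp]] - oracle[[cmp]]) / scale, 1e-6)
    }
  }
})

test_that("chi components are smooth in theta and linear in Ns", {
  b <- helix_beta(26)
  th <- seq(0, 85, by = 0.5)
  vals <- vapply(th, function(t) chi_lab(b, t)$total$zzz, numeric(1))
  expect_true(all(abs(diff(vals)) < 0.1 * max(abs(vals))))
  c1 <- chi_lab(b, 30, Ns = 1)$total
  c5 <- chi_lab(b, 30, Ns = 5)$total
  expect_equal(unlist(c5), 5 * unlist(c1), tolerance = 1e-12)
})

test_that("gaussian tilt distributions recover the delta limit", {
  b <- helix_beta(26)
  narrow <- chi_lab(b, 30, distribution = "gaussian", width = 0.01)
  delta <- chi_lab(b, 30)
  expect_equal(unlist(narrow$total), unlist(delta$total),
               tolerance = 1e-4)
})

test_that("index-matched Fresnel factors are unity", {
  g <- optical_geometry(n1 = 1, n2 = 1, n_interface = 1,
                        angle_vis = 5, angle_ir = 5, angle_sfg = 5)
  L <- fresnel_factors(g)
  for (b in c("sfg", "vis", "ir")) {
    expect_equal(Mod(L[[b]][["xx"]]), 1, tolerance = 1e-10)
    expect_equal(Mod(L[[b]][["yy"]]), 1, tolerance = 1e-10)
  }
})

test_that("each beam's Fresnel factors depend only on its own angle", {
  g1 <- optical_geometry(angle_ir = 54, angle_sfg = 59)
  g2 <- optical_geometry(angle_ir = 45, angle_sfg = 59)
  L1 <- fresnel_factors(g1)
  L2 <- fresnel_factors(g2)
  expect_identical(L1$vis, L2$vis)
  expect_identical(L1$sfg, L2$sfg)
  expect_false(isTRUE(all.equal(L1$ir, L2$ir)))
})

test_that("Fresnel factors match an independent reflection-coefficient route", {
  g <- optical_geometry()
  L <- fresnel_factors(g)
  for (b in c("sfg", "vis", "ir")) {
    n1 <- g$n1[[b]]; n2 <- g$n2[[b]]; np <- g$n_interface[[b]]
    bet <- g$angles[[b]] * pi / 180
    cb <- cos(bet)
    cg <- sqrt(as.complex(1 - (n1 * sin(bet) / n2)^2))
    r_s <- (n1 * cb - n2 * cg) / (n1 * cb + n2 * cg)
    r_p <- (n2 * cb - n1 * cg) / (n2 * cb + n1 * cg)
    expect_equal(L[[b]][["yy"]], 1 + r_s, tolerance = 1e-12)
    expect_equal(L[[b]][["xx"]], 1 - r_p, tolerance = 1e-12)
    expect_equal(L[[b]][["zz"]], (1 + r_p) * (n1 / np)^2,
                 tolerance = 1e-12)
  }
})

test_that("the critical angle is rejected with advice", {
  crit <- asin(1.33 / 1.43) * 180 / pi
  g <- optical_geometry(angle_vis = crit, angle_sfg = 59)
  expect_error(fresnel_factors(g), "critical angle")
})

test_that("a pure-xxz film reduces to the analytic angle combination", {
  chi <- structure(list(
    total = list(xxz = 2.7, xzx = 0, zxx = 0, zzz = 0),
    tilt = 20, distribution = "delta", Ns = 1), class = "chi_surface")
  ang <- 40
  g <- optical_geometry(n1 = 1, n2 = 1, n_interface = 1,
                        angle_vis = ang, angle_ir = ang, angle_sfg = ang)
  L <- fresnel_factors(g)
  got <- effective_ratio(chi, L, g)
  a <- ang * pi / 180
  expect_equal(got, -cos(a)^2, tolerance = 1e-10)
})

test_that("the ratio is undefined when chi_ssp vanishes", {
  chi <- chi_lab(helix_beta(26), 90)
  g <- optical_geometry()
  expect_error(effective_ratio(chi, fresnel_factors(g), g),
               class = "sfgtilt_ratio_undefined")
})

test_that("the effective ratio is homogeneous of degree zero in chi", {
  g <- optical_geometry()
  L <- fresnel_factors(g)
  chi <- chi_lab(helix_beta(26), 25)
  chik <- chi
  chik$total <- lapply(chi$total, function(v) v * -4.2)
  expect_equal(effective_ratio(chik, L, g), effective_ratio(chi, L, g),
               tolerance = 1e-12)
})

test_that("orientation curves for N = 17..21 are pairwise distinct", {
  grid <- seq(0, 60, by = 5)
  curves <- lapply(17:21, ratio_curve, theta_grid = grid)
  for (i in 1:4) {
    for (j in (i + 1):5) {
      expect_gt(max(abs(curves[[i]]$ratio - curves[[j]]$ratio)), 1e-6)
    }
  }
})

test_that("the default curve is strictly monotone on [0, 60] degrees", {
  oc <- ratio_curve(26, theta_grid = seq(0, 60, by = 0.1))
  expect_true(all(oc$defined))
  d <- diff(oc$ratio)
  expect_true(all(d > 0) || all(d < 0))
})

test_that("curves are deterministic and independent of unit strength", {
  oc1 <- ratio_curve(20, theta_grid = seq(0, 80, by = 1))
  oc2 <- ratio_curve(20, theta_grid = seq(0, 80, by = 1))
  expect_identical(oc1$ratio, oc2$ratio)
  oc3 <- ratio_curve(20, params = unit_tensor_params(unit_strength = 40),
                     theta_grid = seq(0, 80, by = 1))
  expect_equal(oc3$ratio, oc1$ratio, tolerance = 1e-12)
})

test_that("curve CSV round-trip supports later inversion", {
  oc <- ratio_curve(26, theta_grid = seq(0, 89, by = 0.5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_orientation_curve(oc, path)
  oc2 <- read_orientation_curve(path)
  expect_equal(oc2$ratio, oc$ratio, tolerance = 1e-9)
  expect_equal(attr(oc2, "n_residues"), 26, ignore_attr = TRUE)
  target <- oc$ratio[oc$theta == 20.5]
  sol <- invert_ratio(list(value = target, sigma = 0), oc2)
  expect_equal(sol$solutions, 20.5, tolerance = 0.05)
})
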