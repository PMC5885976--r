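# rotate a rank-3 tensor: out[I,J,K] = sum R[I,i] R[J,j] R[K,k] b[i,j,k]
apply_rot3 <- function(beta, R) {
  b <- beta
  for (axis in 1:3) {
    m <- matrix(aperm(b, c(axis, setdiff(1:3, axis))), nrow = 3)
    m <- R %*% m
    b <- aperm(array(m, c(3, 3, 3)),
               order(c(axis, setdiff(1:3, axis))))
  }
  b
}

rot_z_test <- function(a) {
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}
rot_y_test <- function(a) {
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}

# brute-force uniform (phi, psi) orientational average of a molecular
# tensor at fixed tilt.  Exploits separability of the z-y-z Euler product:
# average over psi first, rotate by theta, then average over phi.
# Equivalent to the full n_grid x n_grid double average.
chi_brute_oracle <- function(beta, theta_deg, n_grid = 720) {
  ang <- (seq_len(n_grid) - 1) * 2 * pi / n_grid
  avg_z <- function(b) {
    acc <- array(0 + 0i, c(3, 3, 3))
    for (a in ang) acc <- acc + apply_rot3(b, rot_z_test(a))
    acc / n_grid
  }
  b1 <- avg_z(beta)
  b2 <- apply_rot3(b1, rot_y_test(theta_deg * pi / 180))
  b3 <- avg_z(b2)
  list(xxz = b3[1, 1, 3], xzx = b3[1, 3, 1], zxx = b3[3, 1, 1],
       zzz = b3[3, 3, 3])
}

# total lab chi components (A + both E1 branches) via the brute oracle
chi_brute_total <- function(beta, theta_deg, n_grid = 720) {
  parts <- lapply(list(beta$A, beta$E1plus, beta$E1minus),
                  chi_brute_oracle, theta_deg = theta_deg,
                  n_grid = n_grid)
  out <- lapply(c(xxz = "xxz", xzx = "xzx", zxx = "zxx", zzz = "zzz"),
                function(cmp) {
    Re(parts[[1]][[cmp]] + parts[[2]][[cmp]] + parts[[3]][[cmp]])
  })
  out
}

# minimal hand-built fit object for testing pure functions of fits
fake_fit <- function(amplitude, center = 1650, halfwidth = 8,
                     polarization = "ssp", converged = TRUE) {
  structure(list(
    resonances = data.frame(amplitude = amplitude, center = center,
                            halfwidth = halfwidth,
                            se_amplitude = NA_real_,
                            se_center = NA_real_,
                            se_halfwidth = NA_real_),
    nonresonant = list(amplitude = 0, phase = 0, se_amplitude = NA_real_),
    scale = 1, residual = 0, converged = converged,
    window = c(1500, 1800), polarization = polarization,
    wavenumber = numeric(0), intensity = numeric(0)
  ), class = "sfg_fit")
}
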