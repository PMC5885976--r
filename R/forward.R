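#' Per-unit amide-I tensor parameters
#'
#' Parameters of the single peptide-unit amide-I oscillator used to build
#' the helix hyperpolarizability: the angle of the transition dipole from
#' the helix axis, the ratio of transverse to longitudinal Raman
#' polarizability derivative of the unit (the unit Raman tensor is taken
#' cylindrical about the transition dipole), and an overall strength that
#' cancels from every ratio.  Defaults are representative literature values
#' for amide-I helix orientation analysis.
#'
#' @param dipole_tilt Angle of the per-unit transition dipole from the
#'   helix axis, degrees (0 < delta < 90).
#' @param raman_ratio Transverse/longitudinal Raman derivative ratio r.
#' @param unit_strength Overall scale (arbitrary units).
#' @return A list of class `"unit_tensor_params"`.
#' @export
unit_tensor_params <- function(dipole_tilt = 38, raman_ratio = 0.32,
                               unit_strength = 1) {
  stopifnot(dipole_tilt > 0, dipole_tilt < 90, is.finite(raman_ratio))
  structure(list(dipole_tilt = dipole_tilt, raman_ratio = raman_ratio,
                 unit_strength = unit_strength),
            class = "unit_tensor_params")
}

#' Optical geometry of the SFG experiment
#'
#' Refractive indices and beam angles of the three-layer
#' (prism / interfacial layer / solution) model used for the Fresnel
#' local-field factors and the effective ssp/ppp susceptibilities.  The
#' defaults describe a CaF2-prism total-internal-reflection style geometry
#' against water: n1 = 1.43 for all beams, n2 = 1.33, interfacial index
#' n' = 1.18 (slab-model interpolation), visible incidence 60 deg, IR
#' incidence 54 deg, and the SFG angle derived from in-plane phase
#' matching (visible 532 nm, IR wavenumber 1650 cm^-1).
#'
#' @param n1 Refractive index of the incidence medium, one value per beam
#'   `c(sfg, vis, ir)` or a scalar.
#' @param n2 Index of the transmitted medium (solution), scalar or per
#'   beam.
#' @param n_interface Interfacial layer index n', scalar or per beam.
#' @param angle_vis,angle_ir Incidence angles of the visible and IR beams,
#'   degrees in (0, 90).
#' @param angle_sfg SFG beam angle, degrees; `NULL` (default) computes it
#'   from phase matching.
#' @param lambda_vis_nm Visible wavelength, nm.
#' @param wavenumber_ir IR wavenumber, cm^-1.
#' @return A list of class `"optical_geometry"` with per-beam vectors
#'   (`sfg`, `vis`, `ir`) of indices and angles.
#' @export
optical_geometry <- function(n1 = 1.43, n2 = 1.33, n_interface = 1.18,
                             angle_vis = 60, angle_ir = 54,
                             angle_sfg = NULL, lambda_vis_nm = 532,
                             wavenumber_ir = 1650) {
  n1 <- rep_len(n1, 3); n2 <- rep_len(n2, 3)
  n_interface <- rep_len(n_interface, 3)
  stopifnot(all(n1 >= 1), all(n2 >= 1), all(n_interface >= 1),
            angle_vis > 0, angle_vis < 90, angle_ir > 0, angle_ir < 90)
  w_vis <- 1e7 / lambda_vis_nm
  w_sfg <- w_vis + wavenumber_ir
  if (is.null(angle_sfg)) {
    # in-plane phase matching of the reflected/transmitted wavevectors
    s <- (w_vis * n1[2] * sin(deg2rad(angle_vis)) +
            wavenumber_ir * n1[3] * sin(deg2rad(angle_ir))) /
      (w_sfg * n1[1])
    if (abs(s) >= 1) {
      stop("phase-matched SFG angle does not exist for this geometry",
           call. = FALSE)
    }
    angle_sfg <- rad2deg(asin(s))
  }
  stopifnot(angle_sfg > 0, angle_sfg < 90)
  structure(list(
    n1 = stats::setNames(n1, c("sfg", "vis", "ir")),
    n2 = stats::setNames(n2, c("sfg", "vis", "ir")),
    n_interface = stats::setNames(n_interface, c("sfg", "vis", "ir")),
    angles = c(sfg = angle_sfg, vis = angle_vis, ir = angle_ir),
    wavenumbers = c(sfg = w_sfg, vis = w_vis, ir = wavenumber_ir)
  ), class = "optical_geometry")
}

#' Molecular-frame hyperpolarizability of the helix amide-I modes
#'
#' Builds the A (axial) and E1 (doubly degenerate transverse) amide-I
#' hyperpolarizability tensors of an alpha-helix from one oscillator per
#' residue.  Unit k sits at helix azimuth psi_k = k * twist; its IR
#' transition dipole makes the angle `dipole_tilt` with the helix c axis,
#' and its Raman tensor is cylindrical about the dipole with
#' transverse/longitudinal ratio `raman_ratio`.  For the exciton mode of
#' azimuthal order m (m = 0 is the A mode, m = +/-1 the E1 pair) the
#' hyperpolarizability is the product of the two collective derivative
#' sums,
#' \deqn{\beta^{(m)}_{ijk} = \frac{1}{N}\Big(\sum_k \alpha'_{k,ij}
#'   e^{-i m \psi_k}\Big)\Big(\sum_l \mu'_{l,k} e^{+i m \psi_l}\Big),}
#' not a sum of per-unit products: the Raman and IR derivatives belong to
#' the same collective normal coordinate.  For an integer number of turns
#' this reduces to the classic axially symmetric A tensor
#' (beta_aac = beta_bbc, beta_ccc) and the off-diagonal E1 tensor;
#' partial turns add the boundary terms that make different helix lengths
#' distinguishable.
#'
#' @param n_residues Number of residues (>= 1).
#' @param params A [unit_tensor_params()].
#' @param geometry A [helix_geometry()] (only the twist is used).
#' @return A list of class `"beta_tensor"` with complex 3x3x3 arrays `A`,
#'   `E1plus` and `E1minus` (molecular frame, index 3 = helix axis;
#'   Raman pair first, IR index last).
#' @export
helix_beta <- function(n_residues, params = unit_tensor_params(),
                       geometry = helix_geometry()) {
  stopifnot(n_residues >= 1)
  delta <- deg2rad(params$dipole_tilt)
  r <- params$raman_ratio
  alpha0 <- diag(c(r, r, 1))
  Sa0 <- matrix(0 + 0i, 3, 3); SaM <- matrix(0 + 0i, 3, 3)
  Sm0 <- rep(0 + 0i, 3); SmP <- rep(0 + 0i, 3)
  for (k in seq_len(n_residues) - 1L) {
    psik <- deg2rad(k * geometry$twist_per_residue)
    R <- rot_z(psik) %*% rot_y(delta)
    alpha <- R %*% alpha0 %*% t(R)
    mu <- as.numeric(R %*% c(0, 0, 1))
    Sa0 <- Sa0 + alpha
    SaM <- SaM + alpha * exp(-1i * psik)
    Sm0 <- Sm0 + mu
    SmP <- SmP + mu * exp(+1i * psik)
  }
  scale <- params$unit_strength / n_residues
  bA <- outer(Sa0, Sm0) * scale
  bE1p <- outer(SaM, SmP) * scale
  structure(list(A = bA, E1plus = bE1p, E1minus = Conj(bE1p),
                 n_residues = n_residues, params = params),
            class = "beta_tensor")
}

# linear map from the achiral beta components to one lab chi component
# under uniform azimuth/twist averaging; M1 = <cos theta>, M3 = <cos^3
# theta>.  Derived once symbolically from the z-y-z Euler product
# averages; only the seven achiral components survive in xxz/xzx/zxx/zzz.
chi_from_beta <- function(beta, M1, M3) {
  S0 <- beta[1, 1, 3] + beta[2, 2, 3]            # aac + bbc
  S1 <- beta[1, 3, 1] + beta[2, 3, 2]            # aca + bcb
  S2 <- beta[3, 1, 1] + beta[3, 2, 2]            # caa + cbb
  ccc <- beta[3, 3, 3]
  list(
    xxz = (M1 + M3) / 4 * S0 - (M1 - M3) / 4 * (S1 + S2) +
      (M1 - M3) / 2 * ccc,
    xzx = -(M1 - M3) / 4 * S0 + (M1 + M3) / 4 * S1 -
      (M1 - M3) / 4 * S2 + (M1 - M3) / 2 * ccc,
    zxx = -(M1 - M3) / 4 * (S0 + S1) + (M1 + M3) / 4 * S2 +
      (M1 - M3) / 2 * ccc,
    zzz = (M1 - M3) / 2 * (S0 + S1 + S2) + M3 * ccc
  )
}

#' Lab-frame susceptibility components at a given tilt
#'
#' Orientationally averages the molecular hyperpolarizability into the
#' independent lab-frame components of an azimuthally isotropic film
#' (chi_xxz = chi_yyz, chi_xzx = chi_zxx = chi_yzy = chi_zyy, chi_zzz).
#' Azimuth and twist are always averaged uniformly; the tilt distribution
#' is a delta function at `theta` (default), a Gaussian of the given width
#' (in theta, degrees, without the spherical sin-theta weight), or fully
#' isotropic.  For the delta case the result is closed-form in cos(theta)
#' and cos^3(theta).
#'
#' @param beta A [helix_beta()] result.
#' @param theta Tilt of the helix axis from the surface normal, degrees.
#' @param distribution `"delta"`, `"gaussian"` or `"isotropic"`.
#' @param width Gaussian width in theta, degrees.
#' @param Ns Surface number density (overall scale).
#' @return A list of class `"chi_surface"` with per-mode and total
#'   components `xxz`, `xzx`, `zxx`, `zzz` (real), plus `tilt`,
#'   `distribution` and `Ns`.
#' @export
chi_lab <- function(beta, theta, distribution = c("delta", "gaussian",
                                                  "isotropic"),
                    width = 10, Ns = 1) {
  stopifnot(inherits(beta, "beta_tensor"))
  distribution <- match.arg(distribution)
  if (distribution != "isotropic") stopifnot(theta >= 0, theta <= 90)
  m <- switch(distribution,
    delta = {
      ct <- cos(deg2rad(theta))
      c(M1 = ct, M3 = ct^3)
    },
    gaussian = {
      stopifnot(width > 0)
      wgt <- function(x) stats::dnorm(x, deg2rad(theta), deg2rad(width))
      # integrate only where the (possibly narrow) Gaussian has mass
      lo <- max(0, deg2rad(theta - 8 * width))
      hi <- min(pi, deg2rad(theta + 8 * width))
      z <- stats::integrate(wgt, lo, hi)$value
      M1 <- stats::integrate(function(x) cos(x) * wgt(x), lo, hi)$value / z
      M3 <- stats::integrate(function(x) cos(x)^3 * wgt(x), lo,
                             hi)$value / z
      c(M1 = M1, M3 = M3)
    },
    isotropic = c(M1 = 0, M3 = 0)
  )
  per_mode <- lapply(list(A = beta$A, E1plus = beta$E1plus,
                          E1minus = beta$E1minus),
                     chi_from_beta, M1 = m[["M1"]], M3 = m[["M3"]])
  total <- lapply(c(xxz = "xxz", xzx = "xzx", zxx = "zxx", zzz = "zzz"),
                  function(cmp) {
    v <- per_mode$A[[cmp]] + per_mode$E1plus[[cmp]] +
      per_mode$E1minus[[cmp]]
    if (abs(Im(v)) > 1e-8 * max(Mod(v), 1)) {
      warning("non-negligible imaginary part in chi component ", cmp,
              call. = FALSE)
    }
    Re(v) * Ns
  })
  structure(list(
    total = total,
    A = lapply(per_mode$A, function(v) Re(v) * Ns),
    E1 = lapply(names(per_mode$E1plus), function(cmp) {
      Re(per_mode$E1plus[[cmp]] + per_mode$E1minus[[cmp]]) * Ns
    }) |> stats::setNames(names(per_mode$E1plus)),
    tilt = if (distribution == "isotropic") NA_real_ else theta,
    distribution = distribution,
    width = if (distribution == "gaussian") width else NA_real_,
    Ns = Ns
  ), class = "chi_surface")
}

#' @export
print.chi_surface <- function(x, ...) {
  cat("<chi_surface> tilt ", x$tilt, " deg (", x$distribution, ")\n",
      sep = "")
  v <- unlist(x$total)
  print(signif(v, 5))
  invisible(x)
}

#' Fresnel local-field factors
#'
#' Diagonal Fresnel/local-field factors L_xx, L_yy, L_zz of the standard
#' three-layer model for each beam (SFG, visible, IR), from the
#' transmission Fresnel coefficients with interfacial index n'.  Beyond
#' the critical angle the factors become complex (total internal
#' reflection); exactly at the critical angle the z factor diverges and an
#' error advises offsetting the angle.
#'
#' @param geometry An [optical_geometry()].
#' @return A list of class `"fresnel_set"`; per beam a complex vector
#'   `c(xx, yy, zz)`.
#' @export
fresnel_factors <- function(geometry) {
  stopifnot(inherits(geometry, "optical_geometry"))
  out <- lapply(c(sfg = "sfg", vis = "vis", ir = "ir"), function(b) {
    n1 <- geometry$n1[[b]]; n2 <- geometry$n2[[b]]
    np <- geometry$n_interface[[b]]
    bet <- geometry$angles[[b]]
    crit <- if (n2 < n1) rad2deg(asin(n2 / n1)) else NA_real_
    if (!is.na(crit) && abs(bet - crit) < 1e-6) {
      stop("incidence angle of the ", b, " beam is at the critical angle (",
           round(crit, 4), " deg); offset it slightly", call. = FALSE)
    }
    br <- deg2rad(bet)
    sg <- n1 * sin(br) / n2
    cg <- sqrt(as.complex(1 - sg^2))   # imaginary beyond TIR
    cb <- cos(br)
    c(xx = 2 * n1 * cg / (n1 * cg + n2 * cb),
      yy = 2 * n1 * cb / (n1 * cb + n2 * cg),
      zz = 2 * n2 * cb / (n1 * cg + n2 * cb) * (n1 / np)^2)
  })
  structure(out, class = "fresnel_set")
}

#' @export
print.fresnel_set <- function(x, ...) {
  for (b in names(x)) {
    v <- x[[b]]
    cat(b, ": ", paste(names(v), "=", signif(v, 4), collapse = "  "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Effective polarized susceptibilities and their ratio
#'
#' Combines lab-frame chi components with Fresnel factors and beam angles
#' into the effective ssp and ppp susceptibilities:
#' \deqn{\chi_{ssp} = L_{yy}^{SFG} L_{yy}^{vis} L_{zz}^{IR}
#'   \sin\beta_{IR}\, \chi_{yyz}}
#' and the standard four-term signed combination for ppp (xxz, xzx, zxx,
#' zzz).  `effective_ratio()` returns the real ratio chi_ppp/chi_ssp and
#' refuses division when chi_ssp vanishes.
#'
#' @param chi A [chi_lab()] result.
#' @param L A [fresnel_factors()] result; set `bare = TRUE` to replace all
#'   Fresnel factors by 1 (keeping the projection angle factors).
#' @param geometry The [optical_geometry()] the factors came from.
#' @param bare Logical; bypass the Fresnel factors.
#' @return `effective_susceptibilities()` returns
#'   `list(ssp, ppp)` (complex); `effective_ratio()` a single real number.
#' @export
effective_susceptibilities <- function(chi, L, geometry, bare = FALSE) {
  stopifnot(inherits(chi, "chi_surface"), inherits(L, "fresnel_set"),
            inherits(geometry, "optical_geometry"))
  if (bare) {
    one <- c(xx = 1 + 0i, yy = 1 + 0i, zz = 1 + 0i)
    L <- structure(list(sfg = one, vis = one, ir = one),
                   class = "fresnel_set")
  }
  a <- deg2rad(geometry$angles)
  x <- chi$total
  ssp <- L$sfg[["yy"]] * L$vis[["yy"]] * L$ir[["zz"]] *
    sin(a[["ir"]]) * x$xxz
  ppp <- -L$sfg[["xx"]] * L$vis[["xx"]] * L$ir[["zz"]] *
    cos(a[["sfg"]]) * cos(a[["vis"]]) * sin(a[["ir"]]) * x$xxz -
    L$sfg[["xx"]] * L$vis[["zz"]] * L$ir[["xx"]] *
    cos(a[["sfg"]]) * sin(a[["vis"]]) * cos(a[["ir"]]) * x$xzx +
    L$sfg[["zz"]] * L$vis[["xx"]] * L$ir[["xx"]] *
    sin(a[["sfg"]]) * cos(a[["vis"]]) * cos(a[["ir"]]) * x$zxx +
    L$sfg[["zz"]] * L$vis[["zz"]] * L$ir[["zz"]] *
    sin(a[["sfg"]]) * sin(a[["vis"]]) * sin(a[["ir"]]) * x$zzz
  list(ssp = ssp, ppp = ppp)
}

#' @rdname effective_susceptibilities
#' @export
effective_ratio <- function(chi, L, geometry, bare = FALSE) {
  eff <- effective_susceptibilities(chi, L, geometry, bare = bare)
  scale <- max(abs(eff$ppp), abs(eff$ssp))
  if (abs(eff$ssp) <= 1e-12 * max(scale, 1)) {
    stop(ratio_undefined_condition(chi$tilt))
  }
  val <- eff$ppp / eff$ssp
  if (abs(Im(val)) > 1e-8 * max(abs(val), 1)) {
    warning("effective ratio has a non-negligible imaginary part; ",
            "returning the real part", call. = FALSE)
  }
  Re(val)
}

ratio_undefined_condition <- function(theta) {
  structure(class = c("sfgtilt_ratio_undefined", "error", "condition"),
            list(message = paste0("chi_ssp vanishes: ratio undefined at ",
                                  "theta = ", theta, " deg"),
                 call = NULL))
}

#' Orientation curve: chi_ppp/chi_ssp versus helix tilt
#'
#' Evaluates the full forward model ([helix_beta()] -> [chi_lab()] ->
#' [effective_ratio()]) on a tilt grid for a helix of `n_residues`
#' residues.  Grid points where the ratio is undefined (chi_ssp = 0) are
#' recorded with `defined = FALSE` rather than dropped.  The returned
#' object retains the forward model so that [invert_ratio()] can refine
#' solutions on the continuous curve.
#'
#' @param n_residues Helix length in residues.
#' @param geometry An [optical_geometry()].
#' @param params A [unit_tensor_params()].
#' @param theta_grid Tilt grid, degrees in \[0, 90).
#' @param helix A [helix_geometry()].
#' @param bare Emit the ratio of bare chi components (Fresnel factors set
#'   to 1) instead of the Fresnel-weighted effective ratio.
#' @param distribution,width Tilt distribution passed to [chi_lab()].
#' @return A data frame of class `"orientation_curve"` with columns
#'   `theta`, `ratio`, `defined`, and attributes carrying the model.
#' @examples
#' oc <- ratio_curve(26, theta_grid = seq(0, 89, by = 1))
#' plot(oc)
#' @export
ratio_curve <- function(n_residues, geometry = optical_geometry(),
                        params = unit_tensor_params(),
                        theta_grid = seq(0, 89.5, by = 0.5),
                        helix = helix_geometry(), bare = FALSE,
                        distribution = "delta", width = 10) {
  stopifnot(all(theta_grid >= 0), all(theta_grid < 90))
  beta <- helix_beta(n_residues, params, helix)
  L <- fresnel_factors(geometry)
  fn <- function(theta) {
    effective_ratio(chi_lab(beta, theta, distribution, width), L,
                    geometry, bare = bare)
  }
  vals <- vapply(theta_grid, function(th) {
    tryCatch(fn(th),
             sfgtilt_ratio_undefined = function(e) NA_real_)
  }, numeric(1))
  out <- data.frame(theta = theta_grid, ratio = vals,
                    defined = !is.na(vals))
  attr(out, "n_residues") <- n_residues
  attr(out, "geometry") <- geometry
  attr(out, "params") <- params
  attr(out, "bare") <- bare
  attr(out, "fn") <- fn
  class(out) <- c("orientation_curve", "data.frame")
  out
}

# continuous evaluation of an orientation curve: exact forward model when
# available (curves built in-session), monotone-spline interpolation for
# curves re-read from disk
curve_function <- function(curve) {
  fn <- attr(curve, "fn")
  if (!is.null(fn)) return(fn)
  ok <- curve$defined
  stats::splinefun(curve$theta[ok], curve$ratio[ok], method = "natural")
}

#' @export
print.orientation_curve <- function(x, ...) {
  cat("<orientation_curve> N = ", attr(x, "n_residues"), ", ",
      nrow(x), " tilt points, ",
      if (isTRUE(attr(x, "bare"))) "bare chi ratio"
      else "Fresnel-weighted ratio", "\n", sep = "")
  ok <- x$defined
  cat("  ratio range: [", signif(min(x$ratio[ok]), 5), ", ",
      signif(max(x$ratio[ok]), 5), "]\n", sep = "")
  invisible(x)
}

#' @export
plot.orientation_curve <- function(x, ...) {
  graphics::plot(x$theta[x$defined], x$ratio[x$defined], type = "l",
                 xlab = "tilt angle (deg)",
                 ylab = expression(chi[ppp] / chi[ssp]),
                 main = paste0("orientation curve, N = ",
                               attr(x, "n_residues")), ...)
  invisible(x)
}

#' Write / read an orientation curve as CSV
#'
#' The curve is stored as `theta_deg, ratio, defined` with a one-line
#' header, plus a JSON sidecar (`<path>.json`) capturing the helix length,
#' optical geometry and unit-tensor parameters.  A re-read curve supports
#' inversion through spline interpolation of the tabulated values.
#'
#' @param curve An [ratio_curve()] result.
#' @param path CSV path.
#' @return `read_orientation_curve()` returns an `"orientation_curve"`;
#'   `write_orientation_curve()` returns `path` invisibly.
#' @export
write_orientation_curve <- function(curve, path) {
  stopifnot(inherits(curve, "orientation_curve"))
  utils::write.csv(
    data.frame(theta_deg = curve$theta, ratio = curve$ratio,
               defined = curve$defined),
    path, row.names = FALSE)
  g <- attr(curve, "geometry")
  jsonlite::write_json(list(
    n_residues = attr(curve, "n_residues"),
    bare = attr(curve, "bare"),
    geometry = list(n1 = as.list(g$n1), n2 = as.list(g$n2),
                    n_interface = as.list(g$n_interface),
                    angles = as.list(g$angles),
                    wavenumbers = as.list(g$wavenumbers)),
    params = unclass(attr(curve, "params"))
  ), paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_orientation_curve
#' @export
read_orientation_curve <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c("theta_deg", "ratio", "defined") %in% names(d)))
  out <- data.frame(theta = d$theta_deg, ratio = d$ratio,
                    defined = as.logical(d$defined))
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    attr(out, "n_residues") <- meta$n_residues
    attr(out, "bare") <- meta$bare
  }
  class(out) <- c("orientation_curve", "data.frame")
  out
}
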