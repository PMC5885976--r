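#' Read a structure snapshot from a PDB file
#'
#' Parses standard ATOM/HETATM records (via \pkg{bio3d}) into a
#' [structure_model()].  HETATM records (e.g. substrate atoms) are
#' retained and flagged; residues are ordered by (residue number,
#' insertion code) within each chain.
#'
#' @param path PDB file path.
#' @return A [structure_model()].
#' @export
read_structure_pdb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) {
                    stop("failed to parse PDB file ", path, ": ",
                         conditionMessage(e), call. = FALSE)
                  })
  a <- pdb$atom
  if (nrow(a) == 0) stop("no atoms in ", path, call. = FALSE)
  ins <- a$insert
  ins[is.na(ins)] <- ""
  o <- order(a$chain, a$resno, ins)
  a <- a[o, ]
  model <- structure_model(data.frame(
    atom = a$elety,
    element = ifelse(is.na(a$elesy) | a$elesy == "",
                     substr(trimws(a$elety), 1, 1), a$elesy),
    resid = a$resno,
    resname = a$resid,
    chain = ifelse(is.na(a$chain), "A", a$chain),
    x = a$x, y = a$y, z = a$z,
    het = a$type == "HETATM",
    stringsAsFactors = FALSE
  ))
  if (nrow(model$atoms[model$atoms$atom == "CA" & !model$atoms$het, ]) == 0) {
    stop("no C-alpha atoms in ", path, call. = FALSE)
  }
  model
}

#' Helix axis of a structure
#'
#' Estimates the helix main axis as the leading principal component of
#' the centered C-alpha coordinates, with the sign chosen so the
#' z-component is non-negative.  Errors out when the two leading
#' variances coincide (axis degenerate).
#'
#' `local_helix_axis()` is an independent estimator -- the normalized mean
#' of consecutive 4-residue window axes (each window axis from the sum of
#' vectors between C-alpha i and i+3) -- useful as a cross-check against
#' end effects.
#'
#' @param model A [structure_model()].
#' @param residue_range Optional `c(first, last)` residue window.
#' @return A unit 3-vector.
#' @export
helix_axis <- function(model, residue_range = NULL) {
  ca <- ca_matrix(model, residue_range)
  if (nrow(ca) < 4) {
    stop("need at least 4 C-alpha atoms to estimate the helix axis",
         call. = FALSE)
  }
  principal_axis(ca)
}

#' @rdname helix_axis
#' @export
local_helix_axis <- function(model, residue_range = NULL) {
  ca <- ca_matrix(model, residue_range)
  n <- nrow(ca)
  if (n < 4) stop("need at least 4 C-alpha atoms", call. = FALSE)
  axes <- vapply(seq_len(n - 3), function(i) {
    v <- ca[i + 3, ] - ca[i, ]
    v / sqrt(sum(v^2))
  }, numeric(3))
  m <- rowMeans(axes)
  m <- m / sqrt(sum(m^2))
  if (m[3] < 0) m <- -m
  m
}

#' Tilt angle of an axis from the surface normal
#'
#' Angle between an axis and the +z surface normal, folded into
#' \[0, 90\] degrees (an axis and its negation describe the same helix
#' orientation): `acos(|axis . z|)`.
#'
#' @param axis Nonzero 3-vector.
#' @return Angle in degrees.
#' @examples
#' tilt_angle(c(0, 0, 1))   # 0
#' tilt_angle(c(1, 0, 0))   # 90
#' @export
tilt_angle <- function(axis) {
  nrm <- sqrt(sum(axis^2))
  if (nrm == 0) stop("zero vector has no direction", call. = FALSE)
  rad2deg(acos(min(abs(axis[3]) / nrm, 1)))
}

# torsion angle p1-p2-p3-p4 in degrees
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  b2u <- b2 / sqrt(sum(b2^2))
  m <- c(n1[2] * b2u[3] - n1[3] * b2u[2],
         n1[3] * b2u[1] - n1[1] * b2u[3],
         n1[1] * b2u[2] - n1[2] * b2u[1])
  rad2deg(atan2(sum(m * n2), sum(n1 * n2)))
}

# per-residue backbone phi/psi table; NA where a flanking atom is missing
backbone_dihedrals <- function(model) {
  a <- model$atoms[!model$atoms$het, ]
  resids <- sort(unique(a$resid))
  getxyz <- function(res, name) {
    row <- a[a$resid == res & a$atom == name, ]
    if (nrow(row) != 1) return(NULL)
    c(row$x, row$y, row$z)
  }
  phi <- psi <- rep(NA_real_, length(resids))
  for (i in seq_along(resids)) {
    res <- resids[i]
    N <- getxyz(res, "N"); CA <- getxyz(res, "CA"); C <- getxyz(res, "C")
    if (is.null(N) || is.null(CA) || is.null(C)) next
    Cprev <- if (i > 1 && resids[i - 1] == res - 1) {
      getxyz(res - 1, "C")
    }
    Nnext <- if (i < length(resids) && resids[i + 1] == res + 1) {
      getxyz(res + 1, "N")
    }
    if (!is.null(Cprev)) phi[i] <- dihedral(Cprev, N, CA, C)
    if (!is.null(Nnext)) psi[i] <- dihedral(N, CA, C, Nnext)
  }
  data.frame(resid = resids, phi = phi, psi = psi)
}

#' Helical fraction of a structure
#'
#' Fraction of residues whose backbone (phi, psi) dihedrals fall in the
#' alpha-helical window (default phi in \[-100, -30\], psi in
#' \[-80, -5\] degrees), computed over residues with both dihedrals
#' defined.  Chain termini and residues with missing backbone atoms are
#' excluded and counted in the `coverage` attribute (fraction of residues
#' assessed).
#'
#' @param model A [structure_model()].
#' @param phi_window,psi_window Alpha-window bounds, degrees.
#' @return The helical fraction as a number in \[0, 1\] with attributes
#'   `n_assessed`, `n_excluded` and `coverage`.
#' @export
helicity_fraction <- function(model, phi_window = c(-100, -30),
                              psi_window = c(-80, -5)) {
  d <- backbone_dihedrals(model)
  ok <- is.finite(d$phi) & is.finite(d$psi)
  n_tot <- nrow(d)
  n_ok <- sum(ok)
  if (n_ok == 0) {
    stop("no residue has both backbone dihedrals defined", call. = FALSE)
  }
  helical <- d$phi[ok] >= phi_window[1] & d$phi[ok] <= phi_window[2] &
    d$psi[ok] >= psi_window[1] & d$psi[ok] <= psi_window[2]
  structure(mean(helical),
            n_assessed = n_ok,
            n_excluded = n_tot - n_ok,
            coverage = n_ok / n_tot)
}

#' Per-residue surface contacts and binding terminus
#'
#' A residue is in contact with the surface when its lowest atom lies
#' below `z_cutoff` above the z = 0 plane.  The binding terminus is `"C"`
#' when the C-terminal half (residues after position floor(n/2)) has more
#' contacts than the N-terminal half, `"N"` in the symmetric case,
#' `"both"` when both halves have at least a third of their residues in
#' contact (or equal nonzero counts), and `"none"` without any contact.
#'
#' @param model A [structure_model()].
#' @param z_cutoff Contact height above the surface plane, Angstrom
#'   (default 4, a typical heavy-atom contact distance).
#' @return A list of class `"contact_report"`: `contacts` (logical, one
#'   per residue), `resid`, `binding_terminus`, `n_contact_n_half`,
#'   `n_contact_c_half`, `z_cutoff`.
#' @export
terminus_contacts <- function(model, z_cutoff = 4) {
  a <- model$atoms[!model$atoms$het, ]
  resids <- sort(unique(a$resid))
  minz <- vapply(resids, function(r) min(a$z[a$resid == r]), numeric(1))
  contacts <- minz < z_cutoff
  n <- length(resids)
  n_half <- seq_len(n) <= floor(n / 2)
  cn <- sum(contacts[n_half])
  cc <- sum(contacts[!n_half])
  frac_n <- cn / sum(n_half)
  frac_c <- cc / sum(!n_half)
  terminus <- if (cn + cc == 0) {
    "none"
  } else if (frac_n >= 1 / 3 && frac_c >= 1 / 3) {
    "both"
  } else if (cc > cn) {
    "C"
  } else if (cn > cc) {
    "N"
  } else {
    "both"
  }
  structure(list(contacts = contacts, resid = resids,
                 binding_terminus = terminus,
                 n_contact_n_half = cn, n_contact_c_half = cc,
                 z_cutoff = z_cutoff),
            class = "contact_report")
}

#' @export
print.contact_report <- function(x, ...) {
  cat("<contact_report> ", sum(x$contacts), "/", length(x$contacts),
      " residues within ", x$z_cutoff, " A of the surface; ",
      "binding terminus: ", x$binding_terminus, "\n", sep = "")
  invisible(x)
}

#' Full pose analysis of a structure snapshot
#'
#' Composes the helix-axis tilt estimate, the helicity fraction, the
#' surface-contact analysis and the pose classification for one snapshot.
#'
#' @param model A [structure_model()] or the path to a PDB file.
#' @param z_cutoff Contact cutoff, Angstrom.
#' @param residue_range Optional residue window for the axis estimate.
#' @param standing_max,lying_threshold Pose boundaries in degrees, see
#'   [classify_pose()].
#' @return A list of class `"pose_report"`: `tilt_deg`,
#'   `helicity_fraction`, `contacts`, `binding_terminus`,
#'   `classification`, `axis`.
#' @examples
#' rep <- analyze_snapshot(make_ideal_helix(26, tilt = 20.9,
#'                                          terminus_down = "C"))
#' rep$classification
#' @export
analyze_snapshot <- function(model, z_cutoff = 4, residue_range = NULL,
                             standing_max = 30, lying_threshold = 80) {
  if (is.character(model)) model <- read_structure_pdb(model)
  stopifnot(inherits(model, "structure_model"))
  axis <- helix_axis(model, residue_range)
  tilt <- tilt_angle(axis)
  hel <- helicity_fraction(model)
  con <- terminus_contacts(model, z_cutoff)
  cls <- classify_pose(tilt, standing_max = standing_max,
                       lying_threshold = lying_threshold)
  structure(list(
    tilt_deg = tilt,
    helicity_fraction = as.numeric(hel),
    helicity_coverage = attr(hel, "coverage"),
    contacts = con$contacts,
    binding_terminus = con$binding_terminus,
    classification = cls$label,
    rationale = cls$rationale,
    axis = axis,
    z_cutoff = z_cutoff
  ), class = "pose_report")
}

#' @export
print.pose_report <- function(x, ...) {
  cat("<pose_report> tilt ", round(x$tilt_deg, 2), " deg, helicity ",
      round(x$helicity_fraction, 3), ", binding terminus ",
      x$binding_terminus, " -> ", x$classification, "\n", sep = "")
  invisible(x)
}

#' Analyze a series of snapshots
#'
#' Runs [analyze_snapshot()] over several structures (a list of models or
#' a directory of PDB files, taken in lexical order) and summarizes the
#' tilt with a circular-aware mean: per-snapshot tilts (already folded
#' into \[0, 90\] degrees) are averaged on the doubled angle
#' (`atan2(mean sin 2t, mean cos 2t) / 2`), which behaves correctly when
#' tilts cluster near either end of the folded range.  The mean, standard
#' deviation, first and last tilt are reported alongside the per-snapshot
#' reports.
#'
#' @param models A list of [structure_model()]s / PDB paths, or a single
#'   directory path containing `*.pdb` files.
#' @param ... Passed to [analyze_snapshot()].
#' @return A list of class `"pose_series"`: `reports`, `tilt_mean_deg`
#'   (circular-aware), `tilt_sd_deg`, `tilt_first_deg`, `tilt_last_deg`,
#'   `n`.
#' @export
analyze_snapshots <- function(models, ...) {
  if (is.character(models) && length(models) == 1 && dir.exists(models)) {
    models <- sort(list.files(models, pattern = "\\.pdb$",
                              full.names = TRUE))
  }
  if (length(models) == 0) stop("no snapshots to analyze", call. = FALSE)
  reports <- lapply(models, analyze_snapshot, ...)
  tilts <- vapply(reports, `[[`, numeric(1), "tilt_deg")
  # circular mean on the doubled angle, folded back into [0, 90]
  t2 <- deg2rad(2 * tilts)
  mean_tilt <- rad2deg(atan2(mean(sin(t2)), mean(cos(t2))) / 2)
  if (mean_tilt < 0) mean_tilt <- mean_tilt + 180
  if (mean_tilt > 90) mean_tilt <- 180 - mean_tilt
  structure(list(
    reports = reports,
    tilt_mean_deg = mean_tilt,
    tilt_sd_deg = stats::sd(tilts),
    tilt_first_deg = tilts[1],
    tilt_last_deg = tilts[length(tilts)],
    n = length(reports)
  ), class = "pose_series")
}

#' @export
print.pose_series <- function(x, ...) {
  cat("<pose_series> ", x$n, " snapshots; mean tilt ",
      round(x$tilt_mean_deg, 2), " deg (sd ", round(x$tilt_sd_deg, 2),
      "), first ", round(x$tilt_first_deg, 2), ", last ",
      round(x$tilt_last_deg, 2), "\n", sep = "")
  invisible(x)
}

#' Write the per-residue contact table as CSV
#'
#' @param report A [terminus_contacts()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_contact_csv <- function(report, path) {
  stopifnot(inherits(report, "contact_report"))
  utils::write.csv(data.frame(resid = report$resid,
                              contact = report$contacts),
                   path, row.names = FALSE)
  invisible(path)
}
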