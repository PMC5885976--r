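#' Ideal alpha-helix scaffold geometry
#'
#' Parameters of the cylindrical alpha-helix model used by
#' [make_ideal_helix()] and by the amide-I exciton summation of
#' [helix_beta()]: axial rise per residue, twist per residue and the
#' C-alpha cylinder radius.  Defaults are textbook alpha-helix values with
#' 3.615 residues per turn (twist 99.59 deg/residue).  The slightly
#' non-commensurate twist matters for the optics: at exactly 100
#' deg/residue the boundary sums of the exciton modes make several
#' different helix lengths produce identical orientation curves, whereas
#' the 3.615-residue periodicity keeps the length family distinguishable.
#'
#' @param rise_per_residue Axial rise per residue in Angstrom (> 0).
#' @param twist_per_residue Rotation about the helix axis per residue in
#'   degrees (0 < twist < 180; the helix is right-handed).
#' @param radius C-alpha distance from the helix axis in Angstrom.
#' @return A list of class `"helix_geometry"`.
#' @export
helix_geometry <- function(rise_per_residue = 1.5,
                           twist_per_residue = 360 / 3.615,
                           radius = 2.3) {
  stopifnot(rise_per_residue > 0,
            twist_per_residue > 0, twist_per_residue < 180,
            radius > 0)
  structure(list(rise_per_residue = rise_per_residue,
                 twist_per_residue = twist_per_residue,
                 radius = radius),
            class = "helix_geometry")
}

# cylindrical placement of backbone atoms relative to the C-alpha helix:
# (radius A, phase offset deg, z offset A), calibrated once against an
# internal-coordinate build at phi = -57, psi = -47, omega = 180.
.backbone_offsets <- list(
  N  = c(1.557, -26.67, -0.919),
  CA = c(NA,      0.00,  0.000),   # radius taken from helix_geometry
  C  = c(1.672,  26.65,  1.069),
  O  = c(1.926,  20.27,  2.257)
)

#' Construct a structure model from an atom table
#'
#' Light-weight container for a peptide structure: a data frame of atoms
#' with names, elements, 1-based residue indices, residue names, chain id,
#' Cartesian coordinates in Angstrom, and a HETATM flag.  The surface
#' convention is the plane z = 0 with the solution at z > 0.
#'
#' @param atoms Data frame with columns `atom`, `element`, `resid`,
#'   `resname`, `chain`, `x`, `y`, `z`, `het`.
#' @return An object of class `"structure_model"`.
#' @export
structure_model <- function(atoms) {
  need <- c("atom", "element", "resid", "resname", "chain",
            "x", "y", "z", "het")
  stopifnot(is.data.frame(atoms), all(need %in% names(atoms)))
  if (nrow(atoms) == 0L) stop("structure has no atoms", call. = FALSE)
  atoms <- atoms[, need]
  structure(list(atoms = atoms), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  pep <- x$atoms[!x$atoms$het, ]
  cat("<structure_model> ", length(unique(pep$resid)), " residues, ",
      nrow(x$atoms), " atoms (", sum(x$atoms$het), " HETATM)\n", sep = "")
  cat("  z range: [", round(min(x$atoms$z), 2), ", ",
      round(max(x$atoms$z), 2), "] A\n", sep = "")
  invisible(x)
}

# C-alpha coordinate matrix (n x 3), peptide atoms only
ca_matrix <- function(model, residue_range = NULL) {
  a <- model$atoms
  a <- a[a$atom == "CA" & !a$het, ]
  if (!is.null(residue_range)) {
    a <- a[a$resid >= residue_range[1] & a$resid <= residue_range[2], ]
  }
  a <- a[order(a$resid), ]
  cbind(a$x, a$y, a$z)
}

#' Generate an ideal alpha-helix at a prescribed orientation
#'
#' Builds a backbone-only (N, C-alpha, C, O) ideal alpha-helix and places
#' it above the surface plane z = 0 so that its principal C-alpha axis --
#' the same axis definition used by [helix_axis()] -- makes the requested
#' tilt angle with the +z surface normal.  The construction is
#' deterministic; a fixed-seed Gaussian coordinate jitter is available to
#' emulate thermal disorder in snapshots.
#'
#' @param n_residues Number of residues (>= 4; below that the helix axis is
#'   ill-defined for the analysis estimator).
#' @param tilt Tilt of the helix axis from the +z surface normal, degrees
#'   in \[0, 90\].
#' @param azimuth Rotation about z applied after tilting, degrees.
#' @param geometry A [helix_geometry()].
#' @param base_z Height of the lowest atom above the surface plane,
#'   Angstrom.
#' @param sequence Optional one-letter sequence (length `n_residues`) used
#'   for residue names; default poly-alanine.
#' @param terminus_down Which terminus points towards the surface when the
#'   helix is tilted: `"N"` (residue 1 lowest, default) or `"C"`.
#' @param jitter_sd Standard deviation of isotropic Gaussian coordinate
#'   jitter, Angstrom (0 = exact geometry).
#' @param seed Integer seed used when `jitter_sd > 0`.
#' @return A [structure_model()].
#' @examples
#' h <- make_ideal_helix(26, tilt = 20.9, azimuth = 45)
#' tilt_angle(helix_axis(h))
#' @export
make_ideal_helix <- function(n_residues, tilt = 0, azimuth = 0,
                             geometry = helix_geometry(), base_z = 2,
                             sequence = NULL,
                             terminus_down = c("N", "C"),
                             jitter_sd = 0, seed = 1L) {
  if (n_residues < 4) {
    stop("n_residues must be >= 4: the helix axis estimator needs at ",
         "least 4 C-alpha atoms", call. = FALSE)
  }
  stopifnot(tilt >= 0, tilt <= 90, jitter_sd >= 0)
  terminus_down <- match.arg(terminus_down)
  if (is.null(sequence)) {
    sequence <- paste(rep("A", n_residues), collapse = "")
  }
  stopifnot(nchar(sequence) == n_residues)
  resnames <- aa1_to_aa3(sequence)

  # spiral along +z, residue 1 at the bottom; negative phase advance gives
  # the right-handed sense (phi ~ -57, psi ~ -47)
  k <- seq_len(n_residues) - 1L
  coords <- list()
  for (at in names(.backbone_offsets)) {
    off <- .backbone_offsets[[at]]
    r <- if (at == "CA") geometry$radius else off[1]
    ph <- -deg2rad(k * geometry$twist_per_residue + off[2])
    coords[[at]] <- cbind(r * cos(ph), r * sin(ph),
                          k * geometry$rise_per_residue + off[3])
  }
  xyz <- do.call(rbind, lapply(seq_len(n_residues), function(i) {
    rbind(coords$N[i, ], coords$CA[i, ], coords$C[i, ], coords$O[i, ])
  }))
  atom_names <- rep(c("N", "CA", "C", "O"), n_residues)
  resid <- rep(seq_len(n_residues), each = 4L)

  if (terminus_down == "C") xyz <- xyz %*% t(rot_x(pi))

  # align the finite-chain principal C-alpha axis exactly onto +z (end
  # effects tilt it slightly off the cylinder axis), then orient
  ca <- xyz[atom_names == "CA", , drop = FALSE]
  ax <- principal_axis(ca)
  xyz <- xyz %*% rotation_between(ax, c(0, 0, 1))
  xyz <- xyz %*% t(rot_y(deg2rad(tilt))) %*% t(rot_z(deg2rad(azimuth)))

  if (jitter_sd > 0) {
    xyz <- xyz + with_seed(seed, matrix(stats::rnorm(length(xyz), 0, jitter_sd),
                                        ncol = 3))
  }
  xyz[, 3] <- xyz[, 3] - min(xyz[, 3]) + base_z

  structure_model(data.frame(
    atom = atom_names,
    element = substr(atom_names, 1, 1),
    resid = resid,
    resname = resnames[resid],
    chain = "A",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    het = FALSE,
    stringsAsFactors = FALSE
  ))
}

# leading principal component of centred rows, sign fixed so z >= 0
principal_axis <- function(xyz) {
  xc <- sweep(xyz, 2, colMeans(xyz))
  sv <- svd(xc)
  if ((sv$d[1] - sv$d[2]) / max(sv$d[1], .Machine$double.eps) < 1e-9) {
    stop("principal axis degenerate: two leading singular values coincide",
         call. = FALSE)
  }
  ax <- sv$v[, 1]
  if (ax[3] < 0) ax <- -ax
  ax
}

# rotation matrix (for row-vector right multiplication, i.e. x %*% R)
# carrying unit vector `from` onto unit vector `to`
rotation_between <- function(from, to) {
  from <- from / sqrt(sum(from^2)); to <- to / sqrt(sum(to^2))
  v <- c(from[2] * to[3] - from[3] * to[2],
         from[3] * to[1] - from[1] * to[3],
         from[1] * to[2] - from[2] * to[1])
  cth <- sum(from * to)
  if (sqrt(sum(v^2)) < 1e-12) {
    if (cth > 0) return(diag(3))
    # antiparallel: rotate pi about any axis orthogonal to `from`
    o <- if (abs(from[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- o - sum(o * from) * from; v <- v / sqrt(sum(v^2))
    K <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
                byrow = TRUE)
    return(t(diag(3) + 2 * K %*% K))
  }
  K <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
              byrow = TRUE)
  R <- diag(3) + K + K %*% K * ((1 - cth) / sum(v^2))
  t(R)
}

# evaluate expr with a temporary RNG state, restoring the caller's stream
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Build a backbone chain from dihedral angles
#'
#' Constructs N, C-alpha, C, O backbone coordinates from per-residue
#' (phi, psi, omega) dihedrals using sequential internal-coordinate
#' placement with standard bond lengths and angles.  Useful for fixtures
#' with non-helical or mixed secondary structure (e.g. an extended chain at
#' phi = psi = 180).
#'
#' @param phi,psi Numeric vectors of backbone dihedrals in degrees, one per
#'   residue (`phi[1]` and `psi[n]` are not geometrically defined and are
#'   ignored).
#' @param omega Peptide-bond dihedral(s), degrees; recycled.
#' @param sequence Optional one-letter sequence; default poly-alanine.
#' @return A [structure_model()].
#' @examples
#' ext <- build_backbone(rep(180, 10), rep(180, 10))
#' helicity_fraction(ext)
#' @export
build_backbone <- function(phi, psi, omega = 180, sequence = NULL) {
  n <- length(phi)
  stopifnot(n >= 2, length(psi) == n)
  omega <- rep_len(omega, n)
  if (is.null(sequence)) sequence <- paste(rep("A", n), collapse = "")
  stopifnot(nchar(sequence) == n)
  resnames <- aa1_to_aa3(sequence)

  # standard backbone geometry (Angstrom / degrees)
  b_NCa <- 1.458; b_CaC <- 1.525; b_CN <- 1.329; b_CO <- 1.231
  a_NCaC <- 111.2; a_CaCN <- 116.2; a_CNCa <- 121.7; a_CaCO <- 120.8

  N <- matrix(NA_real_, n, 3); CA <- N; CC <- N; O <- N
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(b_NCa, 0, 0)
  ang <- deg2rad(a_NCaC)
  CC[1, ] <- CA[1, ] + b_CaC * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(n)[-1]) {
    N[i, ]  <- place_atom(N[i - 1, ], CA[i - 1, ], CC[i - 1, ],
                          b_CN, a_CaCN, psi[i - 1])
    CA[i, ] <- place_atom(CA[i - 1, ], CC[i - 1, ], N[i, ],
                          b_NCa, a_CNCa, omega[i - 1])
    CC[i, ] <- place_atom(CC[i - 1, ], N[i, ], CA[i, ],
                          b_CaC, a_NCaC, phi[i])
  }
  for (i in seq_len(n)) {
    # carbonyl O trans to the next N across the C(=O)-N bond
    O[i, ] <- place_atom(N[i, ], CA[i, ], CC[i, ], b_CO, a_CaCO,
                         psi[i] - 180)
  }
  xyz <- do.call(rbind, lapply(seq_len(n), function(i) {
    rbind(N[i, ], CA[i, ], CC[i, ], O[i, ])
  }))
  atom_names <- rep(c("N", "CA", "C", "O"), n)
  structure_model(data.frame(
    atom = atom_names,
    element = substr(atom_names, 1, 1),
    resid = rep(seq_len(n), each = 4L),
    resname = resnames[rep(seq_len(n), each = 4L)],
    chain = "A",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    het = FALSE,
    stringsAsFactors = FALSE
  ))
}

# NeRF placement: new atom bonded to c with bond length, angle b-c-new and
# torsion a-b-c-new (degrees); the sign flip makes the realized dihedral
# equal the requested torsion under the IUPAC convention
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- deg2rad(angle); tor <- deg2rad(-torsion)
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  nrm <- c(ab[2] * bc[3] - ab[3] * bc[2],
           ab[3] * bc[1] - ab[1] * bc[3],
           ab[1] * bc[2] - ab[2] * bc[1])
  nrm <- nrm / sqrt(sum(nrm^2))
  m <- c(nrm[2] * bc[3] - nrm[3] * bc[2],
         nrm[3] * bc[1] - nrm[1] * bc[3],
         nrm[1] * bc[2] - nrm[2] * bc[1])
  d <- c(-bond * cos(ang), bond * sin(ang) * cos(tor),
         bond * sin(ang) * sin(tor))
  c + d[1] * bc + d[2] * m + d[3] * nrm
}

#' Write a structure model to a PDB file
#'
#' Standard ATOM records, 1-based residue numbering, occupancy 1.00 and
#' B-factor 0.00.  HETATM-flagged atoms are written as HETATM records.
#'
#' @param model A [structure_model()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(model, path) {
  a <- model$atoms
  xyz <- as.numeric(t(cbind(a$x, a$y, a$z)))
  bio3d::write.pdb(file = path, xyz = xyz,
                   type = ifelse(a$het, "HETATM", "ATOM"),
                   resno = a$resid, resid = a$resname,
                   eleno = seq_len(nrow(a)), elety = a$atom,
                   chain = a$chain,
                   o = rep(1, nrow(a)), b = rep(0, nrow(a)),
                   elesy = a$element)
  invisible(path)
}
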