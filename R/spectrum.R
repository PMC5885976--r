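#' Polarized SFG intensity spectrum
#'
#' Container for an SFG intensity spectrum sampled on a strictly increasing
#' wavenumber grid, tagged with its polarization combination (`ssp` or
#' `ppp`).
#'
#' @param wavenumber Strictly increasing numeric grid, cm^-1.
#' @param intensity Numeric intensities (arbitrary units), same length.
#' @param polarization `"ssp"` or `"ppp"`.
#' @return An object of class `"sfg_spectrum"`.
#' @export
sfg_spectrum <- function(wavenumber, intensity, polarization) {
  stopifnot(length(wavenumber) == length(intensity),
            length(wavenumber) > 0)
  polarization <- match.arg(polarization, c("ssp", "ppp"))
  if (any(!is.finite(wavenumber)) || any(!is.finite(intensity))) {
    stop("non-finite values in spectrum", call. = FALSE)
  }
  if (any(diff(wavenumber) <= 0)) {
    stop("wavenumber grid must be strictly increasing", call. = FALSE)
  }
  structure(list(wavenumber = wavenumber, intensity = intensity,
                 polarization = polarization),
            class = "sfg_spectrum")
}

#' @export
print.sfg_spectrum <- function(x, ...) {
  cat("<sfg_spectrum> ", x$polarization, ", ", length(x$wavenumber),
      " points, ", min(x$wavenumber), "-", max(x$wavenumber), " cm-1\n",
      sep = "")
  invisible(x)
}

#' @export
plot.sfg_spectrum <- function(x, ...) {
  graphics::plot(x$wavenumber, x$intensity, type = "l",
                 xlab = expression(paste("wavenumber (", cm^-1, ")")),
                 ylab = "SFG intensity (a.u.)",
                 main = paste0("SFG spectrum (", x$polarization, ")"), ...)
  invisible(x)
}

# squared modulus of the nonresonant + Lorentzian interference model:
# I(w) = | A_nr e^{i phi} + sum_q A_q / (w - w_q + i G_q) |^2
interference_intensity <- function(w, amplitude, center, halfwidth,
                                   nr_amplitude = 0, nr_phase = 0) {
  field <- complex(real = nr_amplitude * cos(nr_phase),
                   imaginary = nr_amplitude * sin(nr_phase))
  field <- rep(field, length(w))
  for (q in seq_along(amplitude)) {
    field <- field + amplitude[q] / complex(real = w - center[q],
                                            imaginary = rep(halfwidth[q],
                                                            length(w)))
  }
  Mod(field)^2
}

#' Specification of a synthetic SFG spectrum
#'
#' Describes the deterministic line-shape content and noise of a synthetic
#' polarized SFG spectrum: signed Lorentzian resonances interfering with a
#' nonresonant background, evaluated as a squared modulus on a wavenumber
#' grid, plus optional additive Gaussian noise.
#'
#' `amide_i_spectrum_spec()` is the package's default amide-I fixture: a
#' single resonance at 1650 cm^-1 (halfwidth 8 cm^-1, amplitude 5) with no
#' nonresonant background, on a 1500--1800 cm^-1 grid at 1 cm^-1 steps --
#' the alpha-helix amide-I band.
#'
#' @param resonances Data frame (or list coercible to one) with columns
#'   `amplitude` (signed), `center` (cm^-1) and `halfwidth` (> 0, cm^-1).
#'   May have zero rows for a background-only spectrum.
#' @param nonresonant_amplitude Nonresonant background amplitude (>= 0).
#' @param nonresonant_phase Nonresonant phase, radians.
#' @param grid Strictly increasing wavenumber grid, cm^-1.
#' @param noise_sd Standard deviation of additive Gaussian intensity noise
#'   (>= 0).
#' @param seed Integer seed used when `noise_sd > 0`.
#' @return A list of class `"synthetic_spectrum_spec"`.
#' @export
synthetic_spectrum_spec <- function(resonances,
                                    nonresonant_amplitude = 0,
                                    nonresonant_phase = 0,
                                    grid = seq(1500, 1800, by = 1),
                                    noise_sd = 0, seed = 1L) {
  resonances <- as.data.frame(resonances)
  if (nrow(resonances) > 0) {
    stopifnot(all(c("amplitude", "center", "halfwidth") %in%
                    names(resonances)),
              all(resonances$halfwidth > 0))
  }
  if (length(grid) == 0) stop("empty wavenumber grid", call. = FALSE)
  stopifnot(all(diff(grid) > 0), noise_sd >= 0,
            nonresonant_amplitude >= 0)
  structure(list(resonances = resonances,
                 nonresonant_amplitude = nonresonant_amplitude,
                 nonresonant_phase = nonresonant_phase,
                 grid = grid, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_spectrum_spec")
}

#' @rdname synthetic_spectrum_spec
#' @param amplitude,center,halfwidth Parameters of the single amide-I
#'   resonance.
#' @export
amide_i_spectrum_spec <- function(amplitude = 5, center = 1650,
                                  halfwidth = 8, ...) {
  synthetic_spectrum_spec(
    resonances = data.frame(amplitude = amplitude, center = center,
                            halfwidth = halfwidth),
    ...
  )
}

#' Generate a synthetic polarized SFG spectrum
#'
#' Evaluates the squared-modulus Lorentzian-interference model of the given
#' [synthetic_spectrum_spec()] on its wavenumber grid and adds Gaussian
#' noise with the spec's seed.  Bit-identical for a fixed spec.
#'
#' @param spec A [synthetic_spectrum_spec()].
#' @param polarization `"ssp"` or `"ppp"` tag for the resulting spectrum.
#' @return An [sfg_spectrum()].
#' @examples
#' s <- synth_spectrum(amide_i_spectrum_spec(), "ssp")
#' s$wavenumber[which.max(s$intensity)]   # 1650
#' @export
synth_spectrum <- function(spec, polarization = "ssp") {
  stopifnot(inherits(spec, "synthetic_spectrum_spec"))
  r <- spec$resonances
  intensity <- interference_intensity(
    spec$grid, r$amplitude %||% numeric(0), r$center %||% numeric(0),
    r$halfwidth %||% numeric(0),
    spec$nonresonant_amplitude, spec$nonresonant_phase)
  if (spec$noise_sd > 0) {
    intensity <- intensity +
      with_seed(spec$seed,
                stats::rnorm(length(intensity), 0, spec$noise_sd))
  }
  sfg_spectrum(spec$grid, intensity, polarization)
}

#' Read and write spectra as two-column CSV
#'
#' Spectra are exchanged as plain two-column CSV
#' (`wavenumber_cm-1,intensity`) with a one-line header; the polarization
#' is recorded in a leading `#`-comment line and should normally also be
#' encoded in the file name.  `read_spectrum()` sorts non-monotone grids
#' with a warning and fails with the offending line number on non-numeric
#' rows.
#'
#' @param spectrum An [sfg_spectrum()].
#' @param path File path.
#' @param polarization Polarization tag for reading; when `NULL` it is
#'   taken from the file's comment line.
#' @return `read_spectrum()` returns an [sfg_spectrum()];
#'   `write_spectrum()` returns `path` invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "sfg_spectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# polarization: ", spectrum$polarization), con)
  writeLines("wavenumber_cm-1,intensity", con)
  writeLines(sprintf("%.10g,%.10g", spectrum$wavenumber,
                     spectrum$intensity), con)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path, polarization = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) == 0) stop("empty spectrum file: ", path, call. = FALSE)
  comment <- grepl("^\\s*#", lines)
  if (is.null(polarization)) {
    pol_line <- grep("polarization:", lines[comment], value = TRUE)
    if (length(pol_line)) {
      polarization <- trimws(sub(".*polarization:", "", pol_line[1]))
    } else {
      stop("polarization neither given nor recorded in the file",
           call. = FALSE)
    }
  }
  body_idx <- which(!comment)
  body <- lines[body_idx]
  if (length(body) && grepl("wavenumber", body[1], ignore.case = TRUE)) {
    body_idx <- body_idx[-1]
    body <- body[-1]
  }
  body_keep <- nzchar(trimws(body))
  body_idx <- body_idx[body_keep]
  body <- body[body_keep]
  if (length(body) == 0) stop("no data rows in ", path, call. = FALSE)
  parts <- strsplit(body, ",")
  w <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 1)))
  i <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2)))
  bad <- which(is.na(w) | is.na(i))
  if (length(bad)) {
    stop("non-numeric spectrum row at line ", body_idx[bad[1]], " of ",
         path, call. = FALSE)
  }
  if (any(diff(w) <= 0)) {
    warning("wavenumber grid not strictly increasing; sorting rows",
            call. = FALSE)
    o <- order(w)
    w <- w[o]; i <- i[o]
    keep <- c(TRUE, diff(w) > 0)
    w <- w[keep]; i <- i[keep]
  }
  sfg_spectrum(w, i, polarization)
}
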