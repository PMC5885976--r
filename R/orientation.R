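#' Invert a measured amplitude ratio to tilt-angle solutions
#'
#' Finds every tilt angle at which the orientation curve equals the
#' measured chi_ppp/chi_ssp value: all sign changes of
#' `curve(theta) - value` on the tabulated grid are bracketed and refined
#' by bisection to `tol` degrees (default 0.01).  The uncertainty interval
#' is obtained by inverting `value - sigma` and `value + sigma` on each
#' monotone branch that contains a solution; widening sigma can only widen
#' the interval.  A value outside the curve's range yields an empty
#' solution list with `out_of_range = TRUE` -- never an error.
#'
#' @param measured A [amplitude_ratio()] result, or a list with elements
#'   `value` and `sigma`.
#' @param curve An orientation curve from [ratio_curve()] (or re-read via
#'   [read_orientation_curve()]); its grid must be finer than 1 degree.
#' @param tol Bisection tolerance in degrees.
#' @return A list of class `"tilt_solution"`: `solutions` (sorted
#'   ascending, degrees), `interval` (`c(lo, hi)` or `NA`),
#'   `out_of_range`, `measured`, and `n_residues` of the curve used.
#' @examples
#' oc <- ratio_curve(26)
#' target <- oc$ratio[oc$theta == 20.5]
#' invert_ratio(list(value = target, sigma = 0), oc)$solutions
#' @export
invert_ratio <- function(measured, curve, tol = 0.01) {
  stopifnot(inherits(curve, "orientation_curve"),
            is.numeric(measured$value))
  sigma <- measured$sigma %||% 0
  if (max(diff(curve$theta)) > 1) {
    stop("orientation-curve grid must be finer than 1 degree",
         call. = FALSE)
  }
  fn <- curve_function(curve)
  ok <- which(curve$defined)
  th <- curve$theta[ok]
  rv <- curve$ratio[ok]

  # maximal monotone runs of the tabulated curve, as index ranges
  runs <- local({
    sgn <- sign(diff(rv))
    # zero-slope segments extend the neighbouring run
    cur <- 0
    starts <- 1L
    for (i in seq_along(sgn)) {
      if (sgn[i] != 0) {
        if (cur != 0 && sgn[i] != cur) starts <- c(starts, i)
        cur <- sgn[i]
      }
    }
    ends <- c(starts[-1], length(rv))
    cbind(start = starts, end = ends)
  })

  # all roots of curve(theta) = target, tagged with their run
  solve_on_curve <- function(target) {
    d <- rv - target
    sols <- numeric(0); run_of <- integer(0)
    hit <- which(d == 0)
    sc <- which(d[-1] * d[-length(d)] < 0)
    for (i in sc) {
      root <- bisect(function(x) fn(x) - target, th[i], th[i + 1], tol)
      sols <- c(sols, root)
      run_of <- c(run_of, which(runs[, "start"] <= i &
                                  runs[, "end"] >= i + 1)[1])
    }
    for (i in hit) {
      sols <- c(sols, th[i])
      run_of <- c(run_of, which(runs[, "start"] <= i &
                                  runs[, "end"] >= i)[1])
    }
    o <- order(sols)
    keep <- !duplicated(round(sols[o], 6))
    list(solutions = sols[o][keep], run = run_of[o][keep])
  }

  # invert target on one monotone run, clamping to the run end when the
  # target leaves the curve's range there
  invert_on_run <- function(run_id, target) {
    i0 <- runs[run_id, "start"]; i1 <- runs[run_id, "end"]
    v0 <- rv[i0]; v1 <- rv[i1]
    if ((target - v0) * (target - v1) <= 0 && v0 != v1) {
      bisect(function(x) fn(x) - target, th[i0], th[i1], tol)
    } else if (abs(target - v0) < abs(target - v1)) {
      th[i0]
    } else {
      th[i1]
    }
  }

  base <- solve_on_curve(measured$value)
  interval <- c(NA_real_, NA_real_)
  if (length(base$solutions)) {
    pts <- base$solutions
    for (k in seq_along(base$solutions)) {
      for (target in c(measured$value - sigma, measured$value + sigma)) {
        pts <- c(pts, invert_on_run(base$run[k], target))
      }
    }
    interval <- c(min(pts), max(pts))
  }
  structure(list(
    solutions = base$solutions,
    interval = interval,
    out_of_range = length(base$solutions) == 0,
    measured = list(value = measured$value, sigma = sigma),
    n_residues = attr(curve, "n_residues")
  ), class = "tilt_solution")
}

bisect <- function(f, a, b, tol) {
  fa <- f(a); fb <- f(b)
  if (fa == 0) return(a)
  if (fb == 0) return(b)
  if (fa * fb > 0) return((a + b) / 2)  # interpolated bracket lost: midpoint
  while (b - a > tol) {
    m <- (a + b) / 2
    fm <- f(m)
    if (fm == 0) return(m)
    if (fa * fm < 0) {
      b <- m; fb <- fm
    } else {
      a <- m; fa <- fm
    }
  }
  (a + b) / 2
}

#' @export
print.tilt_solution <- function(x, ...) {
  if (x$out_of_range) {
    cat("<tilt_solution> no solution: measured ratio ",
        signif(x$measured$value, 5), " is outside the model range\n",
        sep = "")
  } else {
    cat("<tilt_solution> solutions at ",
        paste(round(x$solutions, 2), collapse = ", "), " deg", sep = "")
    if (all(is.finite(x$interval))) {
      cat("  interval (", round(x$interval[1], 2), ", ",
          round(x$interval[2], 2), ") deg", sep = "")
    }
    cat("\n")
  }
  invisible(x)
}

#' Classify the adsorbed pose of a helix
#'
#' Maps tilt-angle information (or the absence of an SFG amide-I signal)
#' to a pose label.  A helix is `standing` when every tilt solution is
#' below `standing_max`, `tilted` between `standing_max` and
#' `lying_threshold`, and `lying` when the tilt reaches
#' `lying_threshold` -- or when no amide-I signal was observed *and*
#' independent evidence (e.g. circular dichroism) shows an adsorbed helix
#' (`helicity_ok = TRUE`): near 90 deg tilt every achiral chi component
#' carries a cos(theta) factor and the signal vanishes.  A missing signal
#' without that evidence is `undetermined`, since an empty surface and a
#' lying film are then indistinguishable.
#'
#' @param tilt A [invert_ratio()] result, a single tilt in degrees, or
#'   `NULL` when `no_signal = TRUE`.
#' @param no_signal Logical: no amide-I signal detected.
#' @param helicity_ok Logical or `NA`: independent evidence that an
#'   alpha-helical peptide is present on the surface.
#' @param standing_max Standing/tilted boundary, degrees (default 30).
#' @param lying_threshold Tilted/lying boundary, degrees (default 80).
#' @return A list of class `"pose_class"` with `label` (one of
#'   `standing`, `tilted`, `lying`, `undetermined`) and `rationale`.
#' @examples
#' classify_pose(20)$label                                  # standing
#' classify_pose(no_signal = TRUE, helicity_ok = TRUE)$label # lying
#' @export
classify_pose <- function(tilt = NULL, no_signal = FALSE,
                          helicity_ok = NA, standing_max = 30,
                          lying_threshold = 80) {
  stopifnot(standing_max < lying_threshold)
  pose <- function(label, why) {
    structure(list(label = label, rationale = why), class = "pose_class")
  }
  if (no_signal) {
    if (isTRUE(helicity_ok)) {
      return(pose("lying",
                  paste("no amide-I signal while an adsorbed helix is",
                        "independently confirmed: all helices lie in the",
                        "surface plane")))
    }
    return(pose("undetermined",
                paste("no amide-I signal and no independent evidence of",
                      "an adsorbed helix: empty surface and lying film",
                      "are indistinguishable")))
  }
  sols <- if (inherits(tilt, "tilt_solution")) tilt$solutions
          else as.numeric(tilt)
  if (length(sols) == 0) {
    return(pose("undetermined", "no tilt solution available"))
  }
  if (max(sols) >= lying_threshold) {
    return(pose("lying", sprintf(
      "tilt solution %.1f deg is at or beyond the lying threshold (%g deg)",
      max(sols), lying_threshold)))
  }
  if (all(sols < standing_max)) {
    return(pose("standing", sprintf(
      "every tilt solution (%s deg) is below %g deg",
      paste(round(sols, 1), collapse = ", "), standing_max)))
  }
  pose("tilted", sprintf(
    "tilt solutions (%s deg) fall between %g and %g deg",
    paste(round(sols, 1), collapse = ", "), standing_max,
    lying_threshold))
}

#' @export
print.pose_class <- function(x, ...) {
  cat("<pose_class> ", x$label, "\n  ", x$rationale, "\n", sep = "")
  invisible(x)
}

#' Compare an experimental tilt solution with a simulated tilt
#'
#' Reports whether a simulation-derived tilt angle falls inside the
#' experimentally determined interval, together with its distance to the
#' interval and to the nearest experimental solution.
#'
#' @param tilt_exp A [invert_ratio()] result (or a list with `solutions`
#'   and `interval`).
#' @param tilt_sim Simulated tilt angle, degrees in \[0, 90\].
#' @param tol Agreement tolerance in degrees: with a degenerate
#'   (zero-sigma) experimental interval, agreement is still declared when
#'   the simulated tilt lies within `tol` of the nearest solution.
#' @return A list of class `"agreement_report"`: `comparable`, `inside`,
#'   `distance_to_interval` (0 when inside), `nearest_solution`,
#'   `distance_to_nearest`, `agree`.
#' @examples
#' sol <- list(solutions = 20, interval = c(15, 25))
#' compare_exp_sim(sol, 20.9)$inside
#' @export
compare_exp_sim <- function(tilt_exp, tilt_sim, tol = 0.5) {
  stopifnot(tilt_sim >= 0, tilt_sim <= 90)
  sols <- tilt_exp$solutions
  if (is.null(sols) || length(sols) == 0) {
    return(structure(list(comparable = FALSE, inside = NA,
                          distance_to_interval = NA_real_,
                          nearest_solution = NA_real_,
                          distance_to_nearest = NA_real_,
                          agree = NA, tilt_sim = tilt_sim),
                     class = "agreement_report"))
  }
  interval <- tilt_exp$interval
  if (is.null(interval) || any(!is.finite(interval))) {
    interval <- range(sols)
  }
  inside <- tilt_sim >= interval[1] && tilt_sim <= interval[2]
  dist_int <- if (inside) 0 else min(abs(tilt_sim - interval))
  j <- which.min(abs(sols - tilt_sim))
  dist_near <- abs(sols[j] - tilt_sim)
  structure(list(comparable = TRUE, inside = inside,
                 distance_to_interval = dist_int,
                 nearest_solution = sols[j],
                 distance_to_nearest = dist_near,
                 agree = inside || dist_near <= tol,
                 tilt_sim = tilt_sim),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  if (!x$comparable) {
    cat("<agreement_report> not comparable (no experimental solution)\n")
    return(invisible(x))
  }
  cat("<agreement_report> simulated tilt ", x$tilt_sim, " deg ",
      if (x$inside) "inside" else
        sprintf("outside (%.1f deg away from)", x$distance_to_interval),
      " the experimental interval; nearest solution ",
      round(x$nearest_solution, 2), " deg; agreement: ",
      if (isTRUE(x$agree)) "yes" else "no", "\n", sep = "")
  invisible(x)
}
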