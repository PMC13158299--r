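# de Casteljau evaluation of a Bezier curve at parameter values t (vector)
bezier_eval <- function(control, t) {
  control <- as.matrix(control)
  out <- matrix(NA_real_, length(t), ncol(control))
  for (ti in seq_along(t)) {
    pts <- control
    tt <- t[ti]
    while (nrow(pts) > 1L)
      pts <- (1 - tt) * pts[-nrow(pts), , drop = FALSE] +
        tt * pts[-1L, , drop = FALSE]
    out[ti, ] <- pts
  }
  out
}

# derivative control points of a Bezier curve
bezier_deriv_control <- function(control) {
  n <- nrow(control) - 1L
  n * (control[-1L, , drop = FALSE] - control[-(n + 1L), , drop = FALSE])
}

#' Sample points along a polynomial Bézier curve
#'
#' Evaluates the Bézier curve defined by `control_points` (de Casteljau) at
#' `n` positions, either uniformly in the curve parameter or — the canonical
#' setting for building gap-filling landmark series, 40 equidistant points —
#' uniformly in arc length, so consecutive arc distances are equal.
#'
#' @param control_points c x 3 matrix (c >= 2) of control points.
#' @param n number of output points (>= 2), endpoints included.
#' @param spacing `"arc_length"` (default) or `"parameter"`.
#' @return n x 3 matrix of points on the curve.
#' @export
bezier_points <- function(control_points, n,
                          spacing = c("arc_length", "parameter")) {
  spacing <- match.arg(spacing)
  control_points <- as.matrix(control_points)
  if (nrow(control_points) < 2L) stop("need at least 2 control points")
  if (n < 2L) stop("n must be >= 2")
  if (spacing == "parameter")
    return(bezier_eval(control_points, seq(0, 1, length.out = n)))
  # dense cumulative arc length, then invert to equal-arc parameters
  m <- 20000L
  tg <- seq(0, 1, length.out = m + 1L)
  dc <- bezier_deriv_control(control_points)
  speed <- sqrt(rowSums(bezier_eval(dc, tg)^2))
  # composite Simpson on consecutive pairs of intervals
  h <- 1 / m
  cum <- numeric(m + 1L)
  mid_t <- (tg[-1L] + tg[-(m + 1L)]) / 2
  mid_speed <- sqrt(rowSums(bezier_eval(dc, mid_t)^2))
  seg <- h / 6 * (speed[-(m + 1L)] + 4 * mid_speed + speed[-1L])
  cum[-1L] <- cumsum(seg)
  total <- cum[m + 1L]
  target <- seq(0, total, length.out = n)
  tt <- stats::approx(cum, tg, xout = target, ties = "ordered")$y
  tt[1L] <- 0; tt[n] <- 1
  out <- bezier_eval(control_points, tt)
  attr(out, "t") <- tt
  out
}

# numerically-integrated arc length of a Bezier curve (quadrature oracle
# users can call; also used internally by tests)
bezier_arc_length <- function(control_points, t0 = 0, t1 = 1) {
  dc <- bezier_deriv_control(as.matrix(control_points))
  f <- function(t) sqrt(rowSums(bezier_eval(dc, t)^2))
  stats::integrate(f, t0, t1, rel.tol = 1e-10)$value
}

#' Build a gap-bridging point grid from three landmark series
#'
#' Reconstructs a surface patch across a gap (e.g. the nasal gap of a
#' laterally compressed cranium) from three roughly parallel landmark series
#' that span it.  Each series is resampled to `n_across` equidistant points
#' along a Bézier curve; the i-th points of the three series are then
#' "inverted" into a transverse triple perpendicular to the gap, a Bézier
#' curve is drawn through each triple, and `n_along` evenly spaced landmarks
#' are sampled along it.  The default 40 x 70 grid yields 2800 points.
#'
#' @param series list of three matrices (>= 2 points each), ordered
#'   consistently along the gap.
#' @param n_across points per longitudinal series (default 40).
#' @param n_along points per transverse curve (default 70).
#' @return (`n_across * n_along`) x 3 point-cloud matrix; attribute `grid`
#'   holds the n_across x n_along x 3 array.
#' @export
build_gap_grid <- function(series, n_across = 40L, n_along = 70L) {
  if (length(series) != 3L) stop("exactly three landmark series are required")
  series <- lapply(series, as.matrix)
  # consistent orientation: mean dot product of chord directions positive
  chords <- vapply(series, function(s) {
    d <- s[nrow(s), ] - s[1L, ]
    d / sqrt(sum(d^2))
  }, numeric(3L))
  dots <- c(sum(chords[, 1L] * chords[, 2L]),
            sum(chords[, 1L] * chords[, 3L]),
            sum(chords[, 2L] * chords[, 3L]))
  if (mean(dots) < 0)
    stop("series have inconsistent orientation along the gap")
  resampled <- lapply(series, bezier_points, n = n_across,
                      spacing = "arc_length")
  grid <- array(NA_real_, c(n_across, n_along, 3L))
  for (i in seq_len(n_across)) {
    triple <- rbind(resampled[[1L]][i, ], resampled[[2L]][i, ],
                    resampled[[3L]][i, ])
    grid[i, , ] <- bezier_points(triple, n_along, spacing = "arc_length")
  }
  out <- matrix(aperm(grid, c(2L, 1L, 3L)), ncol = 3L)
  attr(out, "grid") <- grid
  out
}
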