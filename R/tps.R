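# 3D thin-plate spline kernel matrix between two point sets (rows = points).
# The 3D biharmonic kernel is linear in the distance; the sign is chosen as
# U(r) = -r so that the kernel is conditionally positive definite and the
# bending-energy quadratic form is non-negative.
tps_kernel <- function(a, b) {
  # distances from explicit coordinate differences: the squared-norm
  # expansion loses ~sqrt(machine eps) absolute accuracy near r = 0, which
  # would corrupt evaluation at the control points themselves
  d2 <- outer(a[, 1L], b[, 1L], `-`)^2 +
    outer(a[, 2L], b[, 2L], `-`)^2 +
    outer(a[, 3L], b[, 3L], `-`)^2
  -sqrt(d2)
}

#' Fit a 3D thin-plate spline
#'
#' Solves the standard TPS interpolation system with the 3D kernel
#' `U(r) = r`: an affine part plus a non-affine part whose weights satisfy
#' the side conditions (zero column sums, orthogonality to the source
#' coordinates).  With `regularization = 0` the map interpolates the targets
#' exactly; the bending energy `trace(W' K W)` is zero exactly when the map
#' is affine.
#'
#' @param source,target m x 3 matrices of corresponding points.
#' @param regularization non-negative ridge added to the kernel diagonal
#'   (smoothing); 0 (default) gives the exact interpolant.
#' @return object of class `tps_transform` with `source_points`,
#'   `target_points`, `affine` (3 x 3), `translation` (length 3), `weights`
#'   (m x 3), `bending_energy` and `bending_matrix` (the m x m quadratic form
#'   whose energy is `trace(Y' B Y)` for any target Y over the same source).
#' @export
tps_fit <- function(source, target, regularization = 0) {
  source <- as.matrix(lm_coords(source))
  target <- as.matrix(lm_coords(target))
  m <- nrow(source)
  if (m < 4L) stop("at least 4 source points are required")
  if (!all(dim(source) == dim(target)))
    stop("source and target dimensions differ")
  if (regularization < 0) stop("regularization must be >= 0")
  dd <- as.matrix(stats::dist(source))
  dup <- which(dd < 1e-12 & upper.tri(dd), arr.ind = TRUE)
  if (nrow(dup) > 0L)
    stop("duplicated source points: ",
         paste(apply(dup, 1L, paste, collapse = "/"), collapse = ", "))
  if (qr(center_config(source), tol = 1e-10)$rank < 3L)
    stop("coplanar source points: the TPS system is singular")
  K <- -dd + diag(regularization, m)
  P <- cbind(1, source)
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 4L, 4L)))
  rhs <- rbind(target, matrix(0, 4L, 3L))
  sol <- tryCatch(solve(L, rhs), error = function(e)
    stop("singular TPS system: ", conditionMessage(e)))
  sol <- sol + solve(L, rhs - L %*% sol)   # one step of iterative refinement
  W <- sol[seq_len(m), , drop = FALSE]
  A <- sol[(m + 2L):(m + 4L), , drop = FALSE]   # 3 x 3, rows act on x,y,z
  b <- sol[m + 1L, ]
  be <- sum(diag(crossprod(W, K %*% W)))
  structure(list(source_points = source, target_points = target,
                 affine = t(A), translation = b, weights = W,
                 bending_energy = abs(be),
                 regularization = regularization),
            class = "tps_transform")
}

#' @export
print.tps_transform <- function(x, ...) {
  cat(sprintf("3D thin-plate spline: %d control points, bending energy %.4g\n",
              nrow(x$source_points), x$bending_energy))
  invisible(x)
}

#' Apply a thin-plate spline to points or a mesh
#'
#' @param t a fitted `tps_transform`.
#' @param x an n x 3 matrix of points, a [landmark_config], or a
#'   [triangle_mesh] (vertices are warped; topology is unchanged).
#' @return warped object of the same kind as `x`.
#' @export
tps_apply <- function(t, x) {
  stopifnot(inherits(t, "tps_transform"))
  if (inherits(x, "triangle_mesh")) {
    x$vertices <- tps_apply(t, x$vertices)
    return(x)
  }
  if (inherits(x, "landmark_config")) {
    x$coords[] <- tps_apply(t, x$coords)
    return(x)
  }
  pts <- as.matrix(x)
  U <- tps_kernel(pts, t$source_points)
  sweep(pts %*% t(t$affine) + U %*% t$weights, 2L, t$translation, `+`)
}

# Bending-energy matrix of a source configuration: the m x m matrix B such
# that the bending energy of the TPS mapping `source` to any target Y is
# trace(Y' B Y).  Upper-left block of the inverse of the bordered system.
bending_energy_matrix <- function(source) {
  source <- as.matrix(source)
  m <- nrow(source)
  K <- tps_kernel(source, source)
  P <- cbind(1, source)
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 4L, 4L)))
  Li <- solve(L)
  B <- Li[seq_len(m), seq_len(m), drop = FALSE]
  (B + t(B)) / 2
}
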