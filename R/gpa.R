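# Optimal proper rotation carrying x onto y (both centered k x 3).
# Reflections are never introduced: det(R) = +1 always.
opa_rotation <- function(x, y) {
  s <- svd(crossprod(x, y))           # x' y = U D V'
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v) # maximizes tr(R' x' y), det = +1
}


#' Generalized Procrustes analysis
#'
#' Iterative superimposition of a sample of 3D landmark configurations:
#' every configuration is centered, scaled to unit centroid size and rotated
#' (proper rotations only) onto the current mean shape; the mean is then
#' recomputed and re-scaled to unit size until it stabilizes.
#'
#' With `scale_mode = "boas"` each aligned configuration is post-multiplied
#' by its original centroid size, yielding Boas (conformation/form space)
#' coordinates: registration without scaling.
#'
#' @param sample a list of [landmark_config] objects (or k x 3 matrices), all
#'   with the same number of landmarks and no missing data.
#' @param scale_mode `"unit_size"` (partial GPA, the default) or `"boas"`.
#' @param metadata optional data.frame of per-specimen covariates (genus,
#'   species, sex, ...) carried along unchanged.
#' @param tol convergence tolerance on the Frobenius change of the mean.
#' @param max_iter iteration cap.
#' @return an object of class `aligned_sample` with elements
#'   `rotated` (k x 3 x n array), `centroid_sizes`, `mean_shape` (k x 3, unit
#'   centroid size, centered), `tangent` (n x 3k tangent coordinates, see
#'   [tangent_projection]), `scale_mode`, `metadata`, `specimen_ids`.
#' @references Gower, J.C. (1975) Generalized Procrustes analysis.
#'   Psychometrika 40, 33-51.
#' @export
gpa <- function(sample, scale_mode = c("unit_size", "boas"), metadata = NULL,
                tol = 1e-10, max_iter = 100L) {
  scale_mode <- match.arg(scale_mode)
  if (inherits(sample, "landmark_config")) sample <- list(sample)
  n <- length(sample)
  if (n < 1L) stop("empty sample")
  mats <- lapply(sample, lm_coords)
  k <- nrow(mats[[1L]])
  if (k < 3L) stop("at least 3 landmarks are required")
  if (any(vapply(mats, nrow, 1L) != k))
    stop("all configurations must share the same number of landmarks")
  if (any(vapply(mats, anyNA, TRUE)))
    stop("missing landmarks present; estimate them before superimposition")
  cs <- vapply(mats, centroid_size, 1.0)
  ids <- vapply(seq_len(n), function(i) {
    s <- sample[[i]]
    if (inherits(s, "landmark_config")) s$specimen_id else paste0("spec", i)
  }, "")

  z <- lapply(mats, preshape)
  for (zi in z)
    if (qr(zi)$rank < 2L) stop("degenerate (rank < 2) configuration")
  mean_shape <- z[[1L]]
  for (it in seq_len(max_iter)) {
    z <- lapply(z, function(zi) zi %*% opa_rotation(zi, mean_shape))
    new_mean <- Reduce(`+`, z) / n
    new_mean <- new_mean / sqrt(sum(new_mean^2))
    delta <- sqrt(sum((new_mean - mean_shape)^2))
    mean_shape <- new_mean
    if (delta < tol) break
  }
  rotated <- array(unlist(z), dim = c(k, 3L, n))
  if (scale_mode == "boas")
    for (i in seq_len(n)) rotated[, , i] <- rotated[, , i] * cs[i]
  dimnames(rotated) <- list(rownames(mats[[1L]]), c("x", "y", "z"), ids)
  out <- structure(list(rotated = rotated,
                        centroid_sizes = cs,
                        mean_shape = mean_shape,
                        scale_mode = scale_mode,
                        metadata = metadata,
                        specimen_ids = ids),
                   class = "aligned_sample")
  if (scale_mode == "unit_size") {
    tp <- tangent_projection(out)
    out$tangent <- tp$tangent
    out$tangent_space_correlation <- tp$correlation
  }
  out
}

#' @export
print.aligned_sample <- function(x, ...) {
  d <- dim(x$rotated)
  cat(sprintf("Procrustes-aligned sample: %d specimens, %d landmarks (%s)\n",
              d[3L], d[1L], x$scale_mode))
  if (!is.null(x$tangent_space_correlation))
    cat(sprintf("  tangent/shape-space distance correlation: %.4f\n",
                x$tangent_space_correlation))
  invisible(x)
}

#' Align a new configuration to an existing GPA
#'
#' Ordinary Procrustes superimposition of one configuration onto the mean
#' shape of a previously computed GPA.  The reference mean and sample
#' statistics are deliberately not recomputed, so the comparative sample is
#' not influenced by the newcomer (e.g. a fossil): an unbiased reference.
#'
#' @param aligned an `aligned_sample` from [gpa()].
#' @param new_config a complete [landmark_config] (or matrix) with the same
#'   number of landmarks.
#' @return list with `coords` (k x 3 aligned, unit centroid size),
#'   `centroid_size` (the specimen's own CS, measured before scaling) and
#'   `tangent` (its tangent-space coordinates relative to the reference mean).
#' @export
align_to_reference <- function(aligned, new_config) {
  stopifnot(inherits(aligned, "aligned_sample"))
  x <- lm_coords(new_config)
  if (anyNA(x)) stop("missing landmarks present")
  if (nrow(x) != nrow(aligned$mean_shape))
    stop("landmark count does not match the reference sample")
  cs <- centroid_size(x)
  z <- preshape(x)
  z <- z %*% opa_rotation(z, aligned$mean_shape)
  m <- aligned$mean_shape
  v <- as.vector(z)
  mv <- as.vector(m)
  tang <- v - sum(v * mv) * mv / sum(mv * mv)
  list(coords = z, centroid_size = cs, tangent = tang)
}

#' Tangent-space projection
#'
#' Orthogonal projection of unit-size Procrustes coordinates onto the linear
#' tangent space of shape space at the sample mean, plus the diagnostic
#' correlation between pairwise tangent (Euclidean) distances and Riemannian
#' shape distances.  For biologically realistic dispersion that correlation
#' is essentially 1 (around 0.999), justifying linear multivariate statistics.
#'
#' @param aligned an `aligned_sample` with `scale_mode = "unit_size"`.
#' @return list with `tangent` (n x 3k matrix; rows are specimens) and
#'   `correlation` (`NA` when n < 3).
#' @export
tangent_projection <- function(aligned) {
  stopifnot(inherits(aligned, "aligned_sample"))
  if (aligned$scale_mode != "unit_size")
    stop("tangent projection requires unit-size Procrustes coordinates")
  n <- dim(aligned$rotated)[3L]
  m <- as.vector(aligned$mean_shape)
  m <- m / sqrt(sum(m^2))
  tang <- t(vapply(seq_len(n), function(i) {
    v <- as.vector(aligned$rotated[, , i])
    v - sum(v * m) * m
  }, numeric(length(m))))
  rownames(tang) <- aligned$specimen_ids
  corr <- NA_real_
  if (n >= 3L) {
    td <- stats::dist(tang)
    rd <- matrix(0, n, n)
    for (i in seq_len(n - 1L))
      for (j in (i + 1L):n)
        rd[i, j] <- riemannian_distance(aligned$rotated[, , i],
                                        aligned$rotated[, , j])
    rd <- stats::as.dist(t(rd))
    corr <- stats::cor(as.vector(td), as.vector(rd))
  }
  list(tangent = tang, correlation = corr)
}

#' Riemannian (Procrustes) shape distance
#'
#' Geodesic distance between two shapes on the preshape sphere:
#' the arc-cosine of the Procrustes inner product of the centered, unit-size
#' preshapes under the optimal proper rotation.  Zero iff the configurations
#' are identical up to translation, rotation and scale; at most pi/2.
#'
#' @param a,b landmark configurations (or k x 3 matrices) with equal k.
#' @return numeric scalar in `[0, pi/2]` (radians).
#' @export
riemannian_distance <- function(a, b) {
  za <- preshape(a)
  zb <- preshape(b)
  if (nrow(za) != nrow(zb)) stop("landmark counts differ")
  # evaluate through the chordal distance under the optimal proper
  # rotation: rho = 2 asin(c / 2) is algebraically identical to
  # acos(sum of singular values) but remains accurate for tiny distances,
  # where the direct arc-cosine loses all precision to cancellation
  R <- opa_rotation(za, zb)
  ch <- sqrt(sum((za %*% R - zb)^2))
  2 * asin(min(1, ch / 2))
}
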