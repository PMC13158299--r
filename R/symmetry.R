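# reflect a k x 3 matrix across the x = 0 plane and swap left/right labels
reflect_relabel <- function(x, pairing) {
  x <- lm_coords(x)
  xm <- x
  xm[, 1L] <- -xm[, 1L]
  xm[relabel_permutation(pairing, nrow(x)), ] <- xm
  xm
}

# ordinary Procrustes superimposition (rotation + translation, no scaling)
# of x onto y; returns the transformed x
opa_rigid <- function(x, y) {
  cx <- colMeans(x); cy <- colMeans(y)
  xc <- sweep(x, 2L, cx)
  yc <- sweep(y, 2L, cy)
  R <- opa_rotation(xc, yc)
  sweep(xc %*% R, 2L, cy, `+`)
}

#' Asymmetry score of a landmark configuration
#'
#' Riemannian shape distance between a configuration and its
#' reflected-relabeled mirror image: zero exactly for object-symmetric
#' configurations, invariant to rigid motion and scaling of the input.
#'
#' @param config [landmark_config] or k x 3 matrix.
#' @param pairing a [pairing_table] covering the configuration.
#' @return non-negative numeric scalar (radians).
#' @export
asymmetry_score <- function(config, pairing) {
  x <- lm_coords(config)
  riemannian_distance(x, reflect_relabel(x, pairing))
}

#' Symmetrize a configuration by reflected relabeling
#'
#' The configuration is mirrored, left/right labels are swapped, the mirror
#' is rigidly superimposed onto the original and the two are averaged; the
#' averaging is repeated until the residual asymmetry falls below `tol`
#' (one pass removes almost all of it; the iteration pins the fixed point).
#' Centroid size is preserved.  Favoured over mirroring along a fitted
#' midsagittal plane because it produces smaller landmark displacements.
#'
#' @inheritParams asymmetry_score
#' @param tol target asymmetry score (default 1e-10).
#' @param max_iter safety cap on averaging passes.
#' @return symmetrized object of the same kind as `config`.
#' @export
symmetrize_reflect_relabel <- function(config, pairing, tol = 1e-10,
                                       max_iter = 50L) {
  x0 <- lm_coords(config)
  if (inherits(config, "landmark_config") && any(config$missing))
    stop("incomplete configuration: estimate missing landmarks first")
  if (!setequal(c(pairing$pairs, pairing$midline), seq_len(nrow(x0))))
    stop("pairing table does not cover the configuration")
  cs <- centroid_size(x0)
  x <- x0
  for (it in seq_len(max_iter)) {
    xm <- reflect_relabel(x, pairing)
    xm <- opa_rigid(xm, x)
    x <- (x + xm) / 2
    if (asymmetry_score(x, pairing) < tol) break
  }
  x <- center_config(x) * (cs / centroid_size(x))
  x <- opa_rigid(x, center_config(x0))
  if (inherits(config, "landmark_config")) {
    config$coords[] <- x
    config
  } else x
}

#' Retrodeform a bilaterally deformed configuration
#'
#' Closed-form retrodeformation using bilateral symmetry: the least-squares
#' affine map carrying the configuration onto its superimposed
#' reflected-relabeled mirror is estimated, and its principal matrix square
#' root — the "halfway" transform — is applied to undo the asymmetric
#' (mirror-odd) component of the plastic deformation.  Residual asymmetry is
#' then removed by reflected-relabeling averaging.  The mirror-even component
#' of a deformation is unobservable from symmetry alone and is left intact.
#' Centroid size is preserved.
#'
#' If the estimated affine map has negative real eigenvalues (no real
#' principal square root), the function falls back to averaging-only
#' symmetrization and records that in the result.
#'
#' @inheritParams asymmetry_score
#' @return object of class `retrodeformation` with `retro_coords` (k x 3),
#'   `affine_estimate`, `halfway_transform`, `asymmetry_before`,
#'   `asymmetry_after`, `fallback` (logical).
#' @export
retrodeform_landmarks <- function(config, pairing) {
  x0 <- lm_coords(config)
  if (inherits(config, "landmark_config") && any(config$missing))
    stop("incomplete configuration: estimate missing landmarks first")
  cs <- centroid_size(x0)
  asym0 <- asymmetry_score(x0, pairing)
  xc <- center_config(x0)
  # canonical frame: rotate so the (approximate) midsagittal normal — the
  # summed left-minus-right pair difference — becomes the x axis; for an
  # object-symmetric configuration this makes it exactly coordinate-plane
  # symmetric, so the closed form below is exact
  nrm <- colSums(xc[pairing$pairs[, 1L], , drop = FALSE] -
                   xc[pairing$pairs[, 2L], , drop = FALSE])
  if (sqrt(sum(nrm^2)) < 1e-10 * cs) {
    sag <- rbind(xc[pairing$midline, , drop = FALSE],
                 (xc[pairing$pairs[, 1L], , drop = FALSE] +
                    xc[pairing$pairs[, 2L], , drop = FALSE]) / 2)
    nrm <- svd(center_config(sag))$v[, 3L]
  }
  nrm <- nrm / sqrt(sum(nrm^2))
  u <- if (abs(nrm[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- u - sum(u * nrm) * nrm
  u <- u / sqrt(sum(u^2))
  v <- c(nrm[2L] * u[3L] - nrm[3L] * u[2L],
         nrm[3L] * u[1L] - nrm[1L] * u[3L],
         nrm[1L] * u[2L] - nrm[2L] * u[1L])
  Q <- cbind(nrm, u, v)                        # proper rotation, n -> e_x
  xr <- xc %*% Q
  xm <- reflect_relabel(xr, pairing)           # coordinate-plane mirror
  # least-squares affine carrying the configuration onto its mirror image
  # (row convention: xm ~ xr %*% M); its principal square root is the
  # halfway transform undoing the mirror-odd deformation component
  M <- solve(crossprod(xr), crossprod(xr, xm))
  ev <- eigen(M, only.values = TRUE)$values
  fallback <- any(Re(ev) <= 0 & abs(Im(ev)) < 1e-12 * max(abs(ev)))
  H <- diag(3)
  if (!fallback) {
    Hs <- tryCatch(pracma::sqrtm(M)$B, error = function(e) NULL)
    if (is.null(Hs) || anyNA(Hs) ||
        max(abs(Hs %*% Hs - M)) > 1e-6 * max(1, max(abs(M)))) {
      fallback <- TRUE
    } else H <- Hs
  }
  xh <- if (fallback) xr else xr %*% H
  xs <- symmetrize_reflect_relabel(xh, pairing)
  xs <- center_config(lm_coords(xs)) * (cs / centroid_size(xs))
  xs <- opa_rigid(xs, center_config(x0))
  xs <- sweep(xs, 2L, colMeans(x0), `+`)
  structure(list(retro_coords = xs,
                 affine_estimate = t(M),
                 halfway_transform = t(H),
                 asymmetry_before = asym0,
                 asymmetry_after = asymmetry_score(xs, pairing),
                 fallback = fallback),
            class = "retrodeformation")
}

#' @export
print.retrodeformation <- function(x, ...) {
  cat(sprintf(
    "Retrodeformation: asymmetry %.3g -> %.3g%s\n",
    x$asymmetry_before, x$asymmetry_after,
    if (x$fallback) " (averaging-only fallback: no real square root)" else ""))
  invisible(x)
}

#' Transfer a landmark retrodeformation (or restoration) to a mesh
#'
#' Warps a triangle mesh by the thin-plate spline fitted from the original
#' landmark positions to their corrected positions; vertices coincident with
#' landmarks land exactly on the corrected landmarks, topology is unchanged.
#'
#' @param mesh a [triangle_mesh].
#' @param original_lms,retro_lms corresponding k x 3 landmark sets (k >= 4,
#'   not coplanar).
#' @return the warped [triangle_mesh].
#' @export
retrodeform_mesh <- function(mesh, original_lms, retro_lms) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  tw <- tps_fit(lm_coords(original_lms), lm_coords(retro_lms))
  tps_apply(tw, mesh)
}

#' @rdname retrodeform_mesh
#' @param target_lms,restored_lms corresponding landmark sets before/after
#'   hyperplane restoration.
#' @export
restore_mesh <- function(mesh, target_lms, restored_lms) {
  retrodeform_mesh(mesh, target_lms, restored_lms)
}
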