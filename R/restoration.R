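#' Reference-hyperplane restoration of a deformed configuration
#'
#' Restores a (retro)deformed target by projecting its shape perpendicularly
#' onto the affine hull of undeformed reference specimens in a principal
#' component framework: references and target are jointly superimposed (GPA),
#' a PCA of the joint tangent coordinates is taken, and the target's score
#' vector within the first `n_pcs` components is replaced by its orthogonal
#' projection onto the affine hull of the reference scores; with three
#' references and `n_pcs = 3` those components carry 100% of the reference
#' variation.  The result is back-transformed to landmark space and rescaled
#' to the target's original centroid size.
#'
#' @param target complete [landmark_config] (or k x 3 matrix); estimate
#'   missing landmarks first.
#' @param references list of >= 3 complete configurations on the same
#'   landmark scheme (symmetrize them beforehand when asymmetry is nuisance
#'   variation).
#' @param n_pcs number of leading principal components spanning the space in
#'   which the projection is performed (default 3).
#' @param include_target logical; include the target in the PCA (default
#'   `TRUE`) or use the references-only eigenstructure.
#' @return object of class `restoration` with `restored_coords` (k x 3, at
#'   the target's original CS), `hyperplane_basis` (orthonormal columns, in
#'   score space), `projection_residual_norm`, `pcs_used`, `scores`
#'   (references then target), `restored_scores`.
#' @export
restore_hyperplane <- function(target, references, n_pcs = 3L,
                               include_target = TRUE) {
  if (length(references) < 3L) stop("at least 3 reference specimens required")
  tx <- lm_coords(target)
  if (anyNA(tx)) stop("target has missing landmarks; estimate them first")
  cs <- centroid_size(tx)
  nref <- length(references)
  al <- gpa(c(references, list(tx)))
  tang <- al$tangent
  m_all <- if (include_target) seq_len(nref + 1L) else seq_len(nref)
  ctr <- colMeans(tang[m_all, , drop = FALSE])
  xc <- sweep(tang, 2L, ctr)
  sv <- svd(xc[m_all, , drop = FALSE])
  keep <- sv$d > max(sv$d) * 1e-10
  avail <- sum(keep)
  if (n_pcs > avail)
    stop("n_pcs = ", n_pcs, " exceeds the ", avail,
         " available components")
  V <- sv$v[, seq_len(n_pcs), drop = FALSE]
  scores <- xc %*% V
  ref_scores <- scores[seq_len(nref), , drop = FALSE]
  t_score <- scores[nref + 1L, ]
  hull_ctr <- colMeans(ref_scores)
  hc <- sweep(ref_scores, 2L, hull_ctr)
  hb <- svd(t(hc))
  hkeep <- hb$d > max(hb$d, 1e-300) * 1e-10
  Q <- hb$u[, hkeep, drop = FALSE]           # orthonormal hull basis
  dev <- t_score - hull_ctr
  proj <- hull_ctr + as.vector(Q %*% crossprod(Q, dev))
  resid_norm <- sqrt(sum((t_score - proj)^2))
  # back-transform: rebuild the restored tangent vector, then invert the
  # orthogonal tangent projection exactly (v = t + sqrt(1 - |t|^2) m is the
  # unit preshape whose tangent coordinates are t)
  new_tang <- ctr + as.vector(V %*% proj)
  m <- as.vector(al$mean_shape)
  m <- m / sqrt(sum(m^2))
  v <- new_tang + sqrt(max(0, 1 - sum(new_tang^2))) * m
  new_shape <- matrix(v, ncol = 3L)
  restored <- center_config(new_shape) * (cs / centroid_size(new_shape))
  structure(list(restored_coords = restored,
                 hyperplane_basis = Q,
                 projection_residual_norm = resid_norm,
                 pcs_used = as.integer(n_pcs),
                 scores = scores,
                 restored_scores = proj,
                 include_target = include_target),
            class = "restoration")
}

#' @export
print.restoration <- function(x, ...) {
  cat(sprintf(
    "Hyperplane restoration: %d PCs, hull dim %d, residual removed %.4g\n",
    x$pcs_used, ncol(x$hyperplane_basis), x$projection_residual_norm))
  invisible(x)
}
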