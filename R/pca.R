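#' Eigenvalue-ratio threshold for meaningful principal components
#'
#' Sequential ratios of adjacent eigenvalues are compared against
#' `exp(2 * sqrt(2 / n))`: components are retained while every ratio up the
#' ladder exceeds the threshold.  At the canonical comparative sample size
#' n = 34 the threshold evaluates to 1.62 (2 d.p.).
#'
#' @param n sample size used to compute the eigenvalues.
#' @return positive numeric scalar.
#' @export
meaningful_pc_threshold <- function(n) {
  stopifnot(n >= 2)
  exp(2 * sqrt(2 / n))
}

#' Shape-space principal component analysis
#'
#' PCA of tangent-space coordinates.  Held-out specimens (e.g. fossils or
#' reconstructions) can be projected onto the sample's component space: they
#' are centered with the sample mean and multiplied by the sample loadings,
#' contributing nothing to the eigenstructure.
#'
#' @param tangent n x p matrix of tangent coordinates (rows = specimens).
#' @param project optional matrix of held-out tangent rows (same p) to
#'   project; or an `aligned_sample`-relative tangent vector.
#' @param threshold eigenvalue-ratio threshold; default
#'   [meaningful_pc_threshold()] at n.
#' @return object of class `shape_pca` with `eigenvalues`, `loadings`
#'   (columns orthonormal), `scores`, `percent_variance`, `n_meaningful`,
#'   `threshold`, `center`, and `projected_scores` when `project` is given.
#' @export
shape_pca <- function(tangent, project = NULL, threshold = NULL) {
  tangent <- as.matrix(tangent)
  n <- nrow(tangent)
  if (n < 3L) stop("need at least 3 specimens for a PCA")
  if (ncol(tangent) < 1L) stop("empty coordinate matrix")
  ctr <- colMeans(tangent)
  xc <- sweep(tangent, 2L, ctr)
  sv <- svd(xc)
  eig <- sv$d^2 / (n - 1)
  keep <- eig > max(eig) * 1e-12
  m <- max(1L, sum(keep))
  eig <- eig[seq_len(m)]
  loadings <- sv$v[, seq_len(m), drop = FALSE]
  scores <- xc %*% loadings
  pct <- 100 * eig / sum(eig)
  if (is.null(threshold)) threshold <- meaningful_pc_threshold(n)
  ratios <- if (m > 1L) eig[-m] / eig[-1L] else numeric(0)
  n_meaningful <- 1L
  for (r in ratios) {
    if (r > threshold) n_meaningful <- n_meaningful + 1L else break
  }
  colnames(scores) <- paste0("PC", seq_len(m))
  out <- structure(list(eigenvalues = eig, loadings = loadings,
                        scores = scores, percent_variance = pct,
                        n_meaningful = n_meaningful, threshold = threshold,
                        center = ctr),
                   class = "shape_pca")
  if (!is.null(project)) {
    pr <- as.matrix(project)
    if (ncol(pr) != length(ctr)) stop("projection rows have wrong dimension")
    out$projected_scores <- sweep(pr, 2L, ctr) %*% loadings
  }
  out
}

#' @export
print.shape_pca <- function(x, ...) {
  cat(sprintf("Shape PCA: %d components, %d meaningful (threshold %.2f)\n",
              length(x$eigenvalues), x$n_meaningful, x$threshold))
  cat("  % variance:",
      paste(sprintf("%.1f", utils::head(x$percent_variance, 5L)),
            collapse = " "),
      if (length(x$percent_variance) > 5L) "..." else "", "\n")
  invisible(x)
}

# matrix correlation between two score/ordination matrices after orthogonal
# Procrustes matching (rotation only); 1 when identical up to rotation/scale.
ordination_fit <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  d <- min(ncol(a), ncol(b))
  a <- a[, seq_len(d), drop = FALSE]
  b <- b[, seq_len(d), drop = FALSE]
  sum(svd(crossprod(a, b))$d) / sqrt(sum(a^2) * sum(b^2))
}

#' Landmark sampling (fit-vs-subset-size) curve
#'
#' Quantifies how much of the among-specimen shape variation an increasing
#' number of landmarks captures relative to the full configuration.  For each
#' of `n_orders` random landmark orderings and each subset size m = 3..k, the
#' subset is re-superimposed and its specimen ordination compared with the
#' full-configuration ordination by matrix correlation after orthogonal
#' Procrustes matching of score matrices.
#'
#' @param aligned an `aligned_sample` (unit size).
#' @param n_orders number of random landmark orderings (default 100).
#' @param seed integer seed for the orderings.
#' @return data.frame with columns `size`, `median_fit`, `lower`, `upper`
#'   (2.5/97.5 percentiles across orderings), plus attribute `fits`
#'   (size x orders matrix).
#' @export
landmark_sampling_curve <- function(aligned, n_orders = 100L, seed = 1L) {
  stopifnot(inherits(aligned, "aligned_sample"))
  k <- dim(aligned$rotated)[1L]
  n <- dim(aligned$rotated)[3L]
  if (k < 4L) stop("need at least 4 landmarks")
  full_scores <- shape_pca(aligned$tangent)$scores
  configs <- lapply(seq_len(n), function(i) aligned$rotated[, , i])
  set.seed(seed)
  sizes <- 3:k
  fits <- matrix(NA_real_, length(sizes), n_orders)
  for (o in seq_len(n_orders)) {
    ord <- sample.int(k)
    for (si in seq_along(sizes)) {
      m <- sizes[si]
      idx <- ord[seq_len(m)]
      if (m == k) {
        fits[si, o] <- 1
        next
      }
      sub <- lapply(configs, function(x) x[idx, , drop = FALSE])
      al <- try(gpa(sub), silent = TRUE)
      if (inherits(al, "try-error")) next
      sub_scores <- shape_pca(al$tangent)$scores
      fits[si, o] <- ordination_fit(sub_scores, full_scores)
    }
  }
  out <- data.frame(size = sizes,
                    median_fit = apply(fits, 1L, stats::median, na.rm = TRUE),
                    lower = apply(fits, 1L, stats::quantile, probs = 0.025,
                                  na.rm = TRUE),
                    upper = apply(fits, 1L, stats::quantile, probs = 0.975,
                                  na.rm = TRUE))
  attr(out, "fits") <- fits
  out
}
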