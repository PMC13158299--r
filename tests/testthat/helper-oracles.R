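# shared oracles and small fixture builders (all generated in code)

# similarity-invariant RMSD between two configurations: both are centered,
# scaled to unit centroid size and optimally rotated (proper rotation) onto
# each other; the root-mean-square landmark distance is returned.  This is a
# direct, GPA-independent implementation used to check recovery claims.
rmsd_similarity <- function(a, b) {
  ctr <- function(x) sweep(x, 2L, colMeans(x))
  za <- ctr(as.matrix(a)); za <- za / sqrt(sum(za^2))
  zb <- ctr(as.matrix(b)); zb <- zb / sqrt(sum(zb^2))
  s <- svd(crossprod(za, zb))
  R <- s$u %*% diag(c(1, 1, sign(det(s$u %*% t(s$v))))) %*% t(s$v)
  sqrt(mean(rowSums((za %*% R - zb)^2)))
}

# random proper rotation
random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9L), 3L)))
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

# apply a random similarity transform (rotation + translation + scale)
random_similarity <- function(x, scale_range = c(0.5, 2)) {
  s <- stats::runif(1L, scale_range[1L], scale_range[2L])
  x %*% random_rotation() * s +
    matrix(stats::rnorm(3L, 0, 10), nrow(x), 3L, byrow = TRUE)
}

# Riemannian distance oracle: optimize the rotation angle triple directly
# (coarse grid + Nelder-Mead refinement), independent of the SVD route
riemann_oracle <- function(a, b) {
  ctr <- function(x) sweep(x, 2L, colMeans(x))
  za <- ctr(as.matrix(a)); za <- za / sqrt(sum(za^2))
  zb <- ctr(as.matrix(b)); zb <- zb / sqrt(sum(zb^2))
  rotmat <- function(th) {
    cx <- cos(th[1L]); sx <- sin(th[1L])
    cy <- cos(th[2L]); sy <- sin(th[2L])
    cz <- cos(th[3L]); sz <- sin(th[3L])
    Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
    Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
    Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
    Rx %*% Ry %*% Rz
  }
  f <- function(th) -sum(za %*% rotmat(th) * zb)
  grid <- as.matrix(expand.grid(th1 = seq(0, 2 * pi, length.out = 7L),
                                th2 = seq(0, pi, length.out = 5L),
                                th3 = seq(0, 2 * pi, length.out = 7L)))
  best <- grid[which.min(apply(grid, 1L, f)), ]
  opt <- stats::optim(best, f, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000L))
  acos(min(1, max(-1, -opt$value)))
}

# tiny 4-landmark toy with one displaced bilateral pair (2 pairs + no
# midline would be degenerate; use 2 pairs + 2 midline points)
toy_pair_config <- function(delta = 1e-4) {
  coords <- rbind(c(-1, 0.3, 0.1), c(1, 0.3, 0.1),
                  c(-0.8, -0.5, 0.2), c(0.8, -0.5, 0.2),
                  c(0, 1, 0), c(0, -1, 0.5))
  coords[1L, 2L] <- coords[1L, 2L] + delta   # displace one left landmark
  pairing <- pairing_table(rbind(c(1L, 2L), c(3L, 4L)), midline = 5:6)
  list(coords = coords, pairing = pairing)
}

# mirror-odd affine shear (the deformation class bilateral retrodeformation
# can invert exactly): x displaced by a transverse direction
random_odd_shear <- function(mag_range = c(0.05, 0.3)) {
  m <- stats::runif(1L, mag_range[1L], mag_range[2L])
  th <- stats::runif(1L, 0, 2 * pi)
  S <- diag(3L)
  S[1L, 2L:3L] <- m * c(cos(th), sin(th))
  S
}
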