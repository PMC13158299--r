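test_that("GPA of a single configuration returns its centered preshape", {
  set.seed(1)
  x <- matrix(rnorm(15), 5L, 3L)
  al <- gpa(list(x))
  expect_equal(sqrt(sum(al$rotated[, , 1L]^2)), 1, tolerance = 1e-9)
  expect_equal(colMeans(al$mean_shape), rep(0, 3L), tolerance = 1e-12)
  expect_lt(riemannian_distance(al$rotated[, , 1L], x), 1e-9)
})

test_that("GPA is invariant to pre-applied similarity transforms", {
  set.seed(2)
  configs <- lapply(1:6, function(i) matrix(rnorm(24), 8L, 3L))
  al1 <- gpa(configs)
  moved <- lapply(configs, random_similarity)
  al2 <- gpa(moved)
  for (i in seq_along(configs))
    expect_lt(riemannian_distance(al1$rotated[, , i], al2$rotated[, , i]),
              1e-8)
  # two copies differing only by a similarity transform coincide
  a <- configs[[1L]]
  al3 <- gpa(list(a, random_similarity(a)))
  expect_lt(riemannian_distance(al3$rotated[, , 1L], al3$rotated[, , 2L]),
            1e-8)
})

test_that("GPA mean matches a direct rotation-optimization oracle", {
  # three hand-written tetrahedra; the oracle optimizes the rotations of
  # configurations 2 and 3 (Euler angles) to minimize the summed squared
  # distance to the arithmetic mean, independent of the GPA iteration
  t1 <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0.2, 0.2, 1))
  t2 <- rbind(c(0, 0, 0.1), c(1.1, 0, 0), c(-0.1, 0.9, 0), c(0.3, 0.1, 0.9))
  t3 <- rbind(c(0.05, -0.05, 0), c(0.9, 0.1, 0), c(0, 1.1, 0.1),
              c(0.25, 0.3, 1.1))
  pre <- lapply(list(t1, t2, t3), function(x) {
    x <- sweep(x, 2L, colMeans(x))
    x / sqrt(sum(x^2))
  })
  rotmat <- function(th) {
    cx <- cos(th[1L]); sx <- sin(th[1L])
    cy <- cos(th[2L]); sy <- sin(th[2L])
    cz <- cos(th[3L]); sz <- sin(th[3L])
    rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx)) %*%
      rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy)) %*%
      rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  }
  obj <- function(th) {
    z <- list(pre[[1L]], pre[[2L]] %*% rotmat(th[1:3]),
              pre[[3L]] %*% rotmat(th[4:6]))
    m <- (z[[1L]] + z[[2L]] + z[[3L]]) / 3
    sum(vapply(z, function(zi) sum((zi - m)^2), 1.0))
  }
  opt <- stats::optim(rep(0.1, 6L), obj, method = "BFGS",
                      control = list(reltol = 1e-15, maxit = 2000L))
  z <- list(pre[[1L]], pre[[2L]] %*% rotmat(opt$par[1:3]),
            pre[[3L]] %*% rotmat(opt$par[4:6]))
  m_oracle <- Reduce(`+`, z) / 3
  m_oracle <- m_oracle / sqrt(sum(m_oracle^2))
  al <- gpa(list(t1, t2, t3))
  expect_lt(riemannian_distance(al$mean_shape, m_oracle), 1e-5)
})

test_that("GPA rejects mismatched or missing-data samples", {
  expect_error(gpa(list(matrix(rnorm(15), 5L), matrix(rnorm(18), 6L))),
               "same number")
  cfg <- landmark_config(matrix(rnorm(15), 5L))
  cfg$coords[1L, ] <- NA
  expect_error(gpa(list(cfg, cfg)), "issing")
})

test_that("aligning to a reference reproduces known positions and sizes", {
  set.seed(3)
  configs <- lapply(1:5, function(i) matrix(rnorm(21), 7L, 3L) +
                      matrix(rnorm(21, 0, 0.05), 7L, 3L))
  al <- gpa(configs)
  # the mean itself, under a random rigid motion, aligns onto the mean
  m_moved <- random_similarity(al$mean_shape)
  out <- align_to_reference(al, m_moved)
  expect_equal(out$coords, al$mean_shape, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(out$centroid_size, centroid_size(m_moved), tolerance = 1e-12)
  # a sample member aligns onto (close to) its own GPA coordinates
  out2 <- align_to_reference(al, configs[[2L]])
  expect_lt(max(abs(out2$coords - al$rotated[, , 2L])), 1e-6)
  expect_error(align_to_reference(al, matrix(rnorm(12), 4L)), "match")
})

test_that("tangent projection is centered at the mean and idempotent", {
  set.seed(4)
  base <- matrix(rnorm(30), 10L, 3L)
  configs <- lapply(1:8, function(i) base + matrix(rnorm(30, 0, 0.01),
                                                  10L, 3L))
  al <- gpa(configs)
  m <- as.vector(al$mean_shape)
  m <- m / sqrt(sum(m^2))
  # the mean maps to the zero tangent vector
  expect_equal(as.vector(m - sum(m * m) * m), rep(0, 30L),
               tolerance = 1e-12)
  # projecting the tangent rows again changes nothing
  reproj <- al$tangent - (al$tangent %*% m) %*% t(m)
  expect_equal(reproj, al$tangent, tolerance = 1e-10, ignore_attr = TRUE)
  # small-dispersion samples live in an essentially flat region
  expect_gte(al$tangent_space_correlation, 0.999)
})

test_that("tangent coordinates conserve total sample variance", {
  set.seed(5)
  base <- matrix(rnorm(24), 8L, 3L)
  configs <- lapply(1:7, function(i) base + matrix(rnorm(24, 0, 0.02),
                                                  8L, 3L))
  al <- gpa(configs)
  tc <- sweep(al$tangent, 2L, colMeans(al$tangent))
  expect_equal(sum(tc^2),
               sum(diag(stats::cov(al$tangent))) * (nrow(tc) - 1L),
               tolerance = 1e-8)
})

test_that("Boas coordinates are unit Procrustes coordinates times CS", {
  set.seed(6)
  configs <- lapply(1:5, function(i) matrix(rnorm(18), 6L, 3L))
  alu <- gpa(configs, scale_mode = "unit_size")
  alb <- gpa(configs, scale_mode = "boas")
  for (i in 1:5)
    expect_equal(alb$rotated[, , i] / alb$centroid_sizes[i],
                 alu$rotated[, , i], tolerance = 1e-12)
})

test_that("Riemannian distance behaves like a shape metric", {
  set.seed(7)
  x <- matrix(rnorm(18), 6L, 3L)
  expect_lt(riemannian_distance(x, random_similarity(x)), 1e-9)
  y <- matrix(rnorm(18), 6L, 3L)
  d0 <- riemannian_distance(x, y)
  expect_equal(riemannian_distance(y, x), d0, tolerance = 1e-12)
  expect_equal(riemannian_distance(x %*% random_rotation(), y), d0,
               tolerance = 1e-9)
  # fixed configurations against the rotation-search oracle
  t1 <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0.4, 0.9))
  t2 <- rbind(c(0, 0.1, 0), c(0.8, 0, 0.2), c(0.1, 1.2, 0), c(0, 0.5, 1))
  expect_equal(riemannian_distance(t1, t2), riemann_oracle(t1, t2),
               tolerance = 1e-6)
})
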