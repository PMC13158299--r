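test_that("slope homogeneity recovers parallel and orthogonal slopes", {
  set.seed(101)
  n <- 40L
  size <- rnorm(n, 100, 10)
  group <- factor(rep(c("a", "b"), each = 20L))
  b <- rnorm(8L); b <- b / sqrt(sum(b^2))
  # identical generating slopes, zero noise: correlation exactly 1
  Y0 <- outer(size, b) + outer(as.integer(group == "b"), rnorm(8L))
  st0 <- slope_homogeneity_test(Y0, size, group, n_perm = 99L, seed = 1L)
  expect_equal(st0$vector_correlation, 1, tolerance = 1e-8)
  expect_equal(st0$angle_deg, 0, tolerance = 1e-4)
  expect_equal(st0$vector_correlation, cos(st0$angle_deg * pi / 180),
               tolerance = 1e-10)
  # orthogonal generating slopes at low noise: angle near 90, small p
  b2 <- rnorm(8L); b2 <- b2 - b * sum(b2 * b); b2 <- b2 / sqrt(sum(b2^2))
  Yo <- Y0
  Yo[group == "b", ] <- outer(size[group == "b"], b2)
  Yo <- Yo + matrix(rnorm(n * 8L, 0, 0.5), n, 8L)
  sto <- slope_homogeneity_test(Yo, size, group, n_perm = 199L, seed = 2L)
  expect_gt(sto$angle_deg, 75)
  expect_lt(sto$p, 0.05)
  expect_error(slope_homogeneity_test(Y0[1:22, ], size[1:22],
                                      factor(c(rep("a", 20L), "b", "b"))),
               "at least 3")
})

test_that("slope-test p-values are calibrated under a common slope", {
  set.seed(102)
  ps <- vapply(1:60, function(r) {
    n <- 30L
    size <- rnorm(n, 100, 10)
    group <- factor(rep(c("a", "b"), each = 15L))
    b <- rnorm(6L)
    Y <- outer(size, b) + matrix(rnorm(n * 6L, 0, 5), n, 6L)
    slope_homogeneity_test(Y, size, group, n_perm = 59L)$p
  }, 1.0)
  # roughly uniform: mean near 0.5, not piling up at small values
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps < 0.05), 0.20)
})

test_that("dispersion homogeneity detects scale differences", {
  set.seed(103)
  Y <- matrix(rnorm(40L * 4L), 40L, 4L)
  grp <- rep(c("a", "b"), each = 20L)
  # same generator: typically not significant
  d0 <- dispersion_homogeneity(Y, grp, n_perm = 199L, seed = 1L)
  expect_gt(d0$p, 0.01)
  # independent route: vegan's spatial-median dispersion test agrees
  bd <- vegan::betadisper(stats::dist(Y), grp, type = "median")
  pt <- vegan::permutest(bd, permutations = 199L)
  expect_equal(d0$F, pt$tab$F[1L], tolerance = 0.02)
  # one group scaled x3: significant in most replicates
  hits <- vapply(1:10, function(r) {
    Yr <- matrix(rnorm(40L * 4L), 40L, 4L)
    Yr[grp == "b", ] <- Yr[grp == "b", ] * 3
    dispersion_homogeneity(Yr, grp, n_perm = 199L)$p < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.9)
  expect_error(dispersion_homogeneity(Y, rep("a", 40L)), "2 groups")
})

test_that("the spatial median of a symmetric cloud is its centroid", {
  set.seed(104)
  X <- matrix(rnorm(50L * 3L), 50L, 3L)
  Xs <- rbind(X, -X)           # centrally symmetric about the origin
  expect_lt(max(abs(spatial_median(Xs))), 1e-6)
  # Weiszfeld minimizes summed distances: nudge and compare
  m <- spatial_median(X)
  f <- function(p) sum(sqrt(rowSums(sweep(X, 2L, p)^2)))
  for (r in 1:5)
    expect_lte(f(m), f(m + rnorm(3L, 0, 0.05)) + 1e-10)
})

test_that("Kendall tau matches enumeration and library oracles", {
  kt <- kendall_tau_test(1:5, 5:1)
  expect_equal(kt$tau, -1, tolerance = 1e-12)
  expect_equal(kendall_tau_test(1:6, 1:6)$tau, 1, tolerance = 1e-12)
  x <- c(1, 2, 3, 4, 5); y <- c(1, 3, 2, 5, 4)
  kt2 <- kendall_tau_test(x, y)
  # brute-force concordance count
  conc <- 0L
  for (i in 1:4) for (j in (i + 1):5)
    conc <- conc + sign(x[j] - x[i]) * sign(y[j] - y[i])
  expect_equal(kt2$tau, conc / choose(5, 2), tolerance = 1e-12)
  ct <- stats::cor.test(x, y, method = "kendall")
  expect_equal(kt2$tau, unname(ct$estimate), tolerance = 1e-10)
  expect_equal(kt2$p, ct$p.value, tolerance = 1e-10)
  # ties fall back to the tie-corrected normal approximation
  kt3 <- kendall_tau_test(c(1, 1, 2, 3, 4, 5, 6, 7, 8, 9),
                          c(2, 1, 3, 3, 5, 4, 7, 8, 6, 9))
  ct3 <- suppressWarnings(stats::cor.test(
    c(1, 1, 2, 3, 4, 5, 6, 7, 8, 9),
    c(2, 1, 3, 3, 5, 4, 7, 8, 6, 9), method = "kendall"))
  expect_equal(kt3$tau, unname(ct3$estimate), tolerance = 1e-10)
  expect_error(kendall_tau_test(rep(1, 5), 1:5), "constant")
})

test_that("VIF and tolerance follow 1/(1 - R^2) exactly", {
  set.seed(105)
  g <- factor(rep(c("a", "b"), each = 12L))
  s <- rnorm(24L) + 2 * (g == "b")
  vt <- vif_tolerance(s, g)
  r2 <- summary(stats::lm(s ~ g))$r.squared
  expect_equal(vt$vif, 1 / (1 - r2), tolerance = 1e-10)
  expect_equal(vt$tolerance, 1 / vt$vif, tolerance = 1e-12)
  # group-independent size: VIF approaches 1 with growing n
  g2 <- factor(rep(c("a", "b"), each = 4000L))
  s2 <- rnorm(8000L)
  expect_lt(vif_tolerance(s2, g2)$vif, 1.01)
  expect_error(vif_tolerance(as.numeric(g == "b"), g), "separation")
})

test_that("predicted shapes follow the coefficient algebra", {
  set.seed(106)
  n <- 30L
  dat <- data.frame(size = rnorm(n, 100, 10),
                    group = factor(rep(c("a", "b"), each = 15L)))
  b_s <- rnorm(5L); b_g <- rnorm(5L)
  Y <- outer(dat$size, b_s) + outer(as.integer(dat$group == "b"), b_g) +
    matrix(rnorm(n * 5L), n, 5L)
  fit <- rrpp_lm(~ size + group, dat, Y, ss_type = "II", n_perm = 99L,
                 seed = 1L)
  s_star <- mean(dat$size)
  ps <- predict_shapes(fit, s_star, n_perm = 49L, seed = 2L)
  B <- fit$coefficients
  oracle_a <- B["(Intercept)", ] + s_star * B["size", ]
  oracle_b <- oracle_a + B["groupb", ]
  expect_equal(ps$predicted["a", ], oracle_a, tolerance = 1e-10)
  expect_equal(ps$predicted["b", ], oracle_b, tolerance = 1e-10)
  expect_warning(predict_shapes(fit, max(dat$size) + 50, n_perm = 9L),
                 "extrapolation")
  # zero group effect: both group predictions collapse to the same shape
  Y0 <- outer(dat$size, b_s) + matrix(rnorm(n * 5L, 0, 1e-8), n, 5L)
  fit0 <- rrpp_lm(~ size + group, dat, Y0, ss_type = "II", n_perm = 9L)
  ps0 <- predict_shapes(fit0, s_star, n_perm = 9L, seed = 3L)
  expect_lt(max(abs(ps0$predicted["a", ] - ps0$predicted["b", ])), 1e-6)
})

test_that("prediction ellipses cover about 95% of replicate means", {
  set.seed(107)
  n <- 40L
  dat <- data.frame(size = rnorm(n, 100, 10),
                    group = factor(rep(c("a", "b"), each = 20L)))
  Y <- outer(dat$size, rnorm(4L)) + matrix(rnorm(n * 4L, 0, 2), n, 4L)
  fit <- rrpp_lm(~ size + group, dat, Y, ss_type = "II", n_perm = 99L,
                 seed = 1L)
  ps <- predict_shapes(fit, mean(dat$size), n_perm = 400L, seed = 2L)
  for (g in c("a", "b")) {
    s <- ps$perm_scores[[g]]
    e <- ps$ellipses[[g]]
    md <- stats::mahalanobis(s, e$center, e$cov)
    cover <- mean(md <= e$radius2)
    expect_gt(cover, 0.90)
    expect_lt(cover, 0.99)
  }
})

test_that("regression scores project onto the size axis", {
  set.seed(108)
  n <- 25L
  size <- rnorm(n, 50, 5)
  b <- rnorm(6L)
  Y <- outer(size, b)
  fit <- rrpp_lm(~ size, data.frame(size = size), Y, n_perm = 9L)
  sc <- regression_scores(fit)
  expect_equal(abs(stats::cor(sc, size)), 1, tolerance = 1e-8)
  # explicit projection oracle
  bhat <- fit$coefficients["size", ]
  oracle <- sweep(Y, 2L, colMeans(Y)) %*% (bhat / sqrt(sum(bhat^2)))
  expect_equal(sc, as.vector(oracle), tolerance = 1e-10)
  # fitted-value PCA has exactly rank(model) - 1 nonzero axes here
  Y2 <- Y + outer(rnorm(n), rnorm(6L)) + matrix(rnorm(n * 6L), n, 6L)
  dat2 <- data.frame(size = size,
                     group = factor(rep(c("a", "b"), c(13L, 12L))))
  fit2 <- rrpp_lm(~ size + group, dat2, Y2, n_perm = 9L)
  fv <- fitted_value_pca(fit2)
  nz <- sum(fv$eigenvalues > max(fv$eigenvalues) * 1e-9)
  expect_identical(nz, 2L)
  expect_equal(sum(fv$percent_variance), 100, tolerance = 1e-6)
})

test_that("size diagnostics bundle matches the base-R oracles", {
  set.seed(109)
  g <- factor(rep(c("a", "b"), c(12L, 8L)))
  s <- c(rnorm(12L, 95, 8), rnorm(8L, 115, 8))
  d <- size_group_diagnostics(s, g, n_mc = 999L, seed = 1L)
  expect_equal(d$bartlett_p, stats::bartlett.test(s, g)$p.value,
               tolerance = 1e-12)
  expect_equal(unname(d$shapiro_p["a"]),
               stats::shapiro.test(s[g == "a"])$p.value, tolerance = 1e-12)
  expect_equal(d$wilcoxon_W,
               unname(stats::wilcox.test(s[g == "a"],
                                         s[g == "b"])$statistic),
               tolerance = 1e-12)
  # disjoint ranges: the Monte-Carlo p bottoms out at 1/(n_mc + 1)
  s2 <- c(rnorm(12L, 0, 1), rnorm(8L, 100, 1))
  d2 <- size_group_diagnostics(s2, g, n_mc = 999L, seed = 2L)
  expect_equal(d2$wilcoxon_p_mc, 1 / 1000, tolerance = 1e-12)
  expect_equal(abs(d2$rank_effect_size), 1, tolerance = 1e-12)
})
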