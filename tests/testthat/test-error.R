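make_trialset <- function(noise_sd = 0.3, n_spec = 3L, n_trials = 4L,
                          seed = 121L, resolution_factor = 1) {
  sim <- simulate_allometric_sample(
    n_per_group = c(max(2L, n_spec - 1L), 2L), seed = seed)
  simulate_digitization_trials(sim$configs[seq_len(n_spec)],
                               noise_sd = noise_sd, n_trials = n_trials,
                               resolution_factor = resolution_factor,
                               seed = seed + 1L)
}

test_that("identical trials produce zero error everywhere", {
  trl <- make_trialset(noise_sd = 0)
  les <- landmark_error_summary(trl)
  expect_lt(max(les$sd_mm), 1e-10)
  expect_false(any(les$above_1mm))
  rd <- trial_riemannian_distances(trl)
  expect_lt(max(vapply(rd, max, 1.0)), 1e-7)
  icc <- procrustes_anova_icc(trl, n_perm = 49L, seed = 1L)
  expect_equal(icc$icc, 1, tolerance = 1e-6)
  expect_equal(icc$me_percent, 0, tolerance = 1e-4)
})

test_that("per-landmark SDs track the injected noise level", {
  trl1 <- make_trialset(noise_sd = 0.3, seed = 122L)
  trl2 <- make_trialset(noise_sd = 0.6, seed = 122L)
  m1 <- stats::median(landmark_error_summary(trl1)$sd_mm)
  m2 <- stats::median(landmark_error_summary(trl2)$sd_mm)
  expect_equal(m2 / m1, 2, tolerance = 0.25)
  # simulation oracle: the same statistic computed directly from the
  # generating model (trial-to-mean distances of iid Gaussian landmarks)
  set.seed(5)
  oracle <- stats::median(replicate(4000L, {
    tr <- matrix(stats::rnorm(4L * 3L, 0, 0.3), 4L, 3L)
    stats::sd(sqrt(rowSums(sweep(tr, 2L, colMeans(tr))^2)))
  }))
  expect_lt(abs(m1 - oracle), 0.15 * oracle)
  # percentage column is consistent
  les <- landmark_error_summary(trl1)
  expect_true(all(les$sd_percent_cs > 0))
  expect_true(any(landmark_error_summary(
    make_trialset(noise_sd = 2.5, seed = 123L))$above_2mm))
})

test_that("an outlier trial dominates the Riemannian distance matrix", {
  trl <- make_trialset(noise_sd = 0.1, n_spec = 2L, seed = 124L)
  # corrupt specimen 1, trial 3
  i <- which(trl$specimen == levels(trl$specimen)[1L] &
               trl$trial == "t3")
  trl$configs[[i]]$coords <- trl$configs[[i]]$coords +
    matrix(stats::rnorm(99L, 0, 5), 33L, 3L)
  rd <- trial_riemannian_distances(trl)[[1L]]
  expect_lt(max(abs(rd - t(rd))), 1e-12)
  expect_identical(unname(which.max(rowSums(rd))),
                   which(colnames(rd) == "t3"))
})

test_that("ICC recovers known among/within variance ratios", {
  tm <- make_template()
  icc_sim <- function(rho, seed) {
    set.seed(seed)
    tot <- 0.8
    sa <- tot * sqrt(rho); sw <- tot * sqrt(1 - rho)
    specs <- lapply(1:8, function(i)
      landmark_config(tm$config$coords +
                        matrix(stats::rnorm(99L, 0, sa), 33L, 3L),
                      specimen_id = paste0("s", i)))
    trl <- simulate_digitization_trials(specs, noise_sd = sw,
                                        n_trials = 4L, seed = seed + 50L)
    procrustes_anova_icc(trl, n_perm = 49L)$icc
  }
  for (rho in c(0.5, 0.9)) {
    est <- vapply(1:5, function(s) icc_sim(rho, s), 1.0)
    ci <- mean(est) + c(-1, 1) * 3 * stats::sd(est) / sqrt(5)
    expect_gt(rho, ci[1L] - 0.02)
    expect_lt(rho, ci[2L] + 0.02)
  }
})

test_that("ICC is invariant to a global rigid motion of all trials", {
  trl <- make_trialset(noise_sd = 0.4, seed = 126L)
  icc0 <- procrustes_anova_icc(trl, n_perm = 49L, seed = 2L)$icc
  R <- random_rotation()
  trl2 <- trl
  trl2$configs <- lapply(trl$configs, function(cfg) {
    cfg$coords <- cfg$coords %*% R +
      matrix(c(10, -5, 3), nrow(cfg$coords), 3L, byrow = TRUE)
    cfg
  })
  icc1 <- procrustes_anova_icc(trl2, n_perm = 49L, seed = 2L)$icc
  expect_equal(icc0, icc1, tolerance = 1e-6)
})

test_that("raw and Boas SDs agree for pure noise, diverge under rotations", {
  trl <- make_trialset(noise_sd = 0.3, seed = 127L)
  raw0 <- stats::median(landmark_error_summary(trl, "raw")$sd_mm)
  boas0 <- stats::median(landmark_error_summary(trl, "boas")$sd_mm)
  expect_lt(abs(raw0 - boas0), 0.35 * raw0)
  # inject per-trial rotations: raw SDs blow up, Boas registration does not
  set.seed(128)
  trl_rot <- trl
  trl_rot$configs <- lapply(trl$configs, function(cfg) {
    th <- stats::runif(1L, 0.2, 0.5)
    Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0),
                c(0, 0, 1))
    cfg$coords <- cfg$coords %*% Rz
    cfg
  })
  raw1 <- stats::median(landmark_error_summary(trl_rot, "raw")$sd_mm)
  boas1 <- stats::median(landmark_error_summary(trl_rot, "boas")$sd_mm)
  expect_gt(raw1, 5 * raw0)
  expect_lt(boas1, 2 * boas0)
})

test_that("blocked MANOVA matches an exhaustive enumeration oracle", {
  set.seed(129)
  # 2 blocks x 4 observations, two labels within each block
  n <- 8L
  blocks <- factor(rep(c("b1", "b2"), each = 4L))
  f <- factor(rep(c("x", "x", "y", "y"), 2L))
  Y <- matrix(stats::rnorm(n * 3L), n, 3L)
  # enumeration oracle: all within-block permutations, pseudo-F on the
  # Euclidean distance matrix (Type I, one factor)
  pseudo_F <- function(fac) {
    G <- stats::model.matrix(~ fac)
    H <- G %*% solve(crossprod(G)) %*% t(G)
    Yc <- sweep(Y, 2L, colMeans(Y))
    ssb <- sum((H %*% Yc)^2)
    ssw <- sum(Yc^2) - ssb
    (ssb / (nlevels(fac) - 1L)) / (ssw / (n - nlevels(fac)))
  }
  perms_b <- retromorph:::all_permutations(4L)
  Fs <- numeric(0)
  for (i in seq_len(nrow(perms_b))) for (j in seq_len(nrow(perms_b))) {
    idx <- c(perms_b[i, ], 4L + perms_b[j, ])
    Fs <- c(Fs, pseudo_F(f[idx]))
  }
  F_obs <- pseudo_F(f)
  p_oracle <- mean(Fs >= F_obs - 1e-12)
  bm <- blocked_manova(Y, f, blocks, n_perm = 9999L, seed = 3L)
  expect_equal(bm$F, F_obs, tolerance = 1e-8)
  expect_equal(bm$p, p_oracle, tolerance = 0.03)
})

test_that("a factor confounded with blocks cannot be significant", {
  set.seed(130)
  n <- 12L
  blocks <- factor(rep(c("b1", "b2"), each = 6L))
  Y <- matrix(stats::rnorm(n * 3L), n, 3L) +
    outer(as.integer(blocks), c(3, 0, -2))
  bm <- blocked_manova(Y, blocks, blocks, n_perm = 199L, seed = 1L)
  expect_gte(bm$p, 0.99)
  expect_error(blocked_manova(Y, blocks, factor(seq_len(n))), "at least 2")
})

test_that("blocked-null p-values are roughly uniform", {
  set.seed(131)
  ps <- vapply(1:40, function(r) {
    n <- 12L
    blocks <- factor(rep(c("b1", "b2"), each = 6L))
    f <- factor(rep(c("x", "y", "z"), 4L))
    Y <- matrix(stats::rnorm(n * 3L), n, 3L)
    blocked_manova(Y, f, blocks, n_perm = 99L)$p
  }, 1.0)
  expect_lte(sum(ps < 0.05), 7L)
  expect_gt(mean(ps), 0.3)
})
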