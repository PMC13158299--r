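# build a small sample with one sliding curve appended to a template
make_curve_sample <- function(n = 4L, jitter = 0.4, seed = 41L) {
  set.seed(seed)
  tm <- make_template(k_pairs = 6L, k_midline = 3L, scale = 50)
  base <- tm$config$coords
  # curve endpoints offset from the anatomical landmarks so that no two
  # TPS source points coincide
  cp <- rbind(base[1L, ] + c(0, 2, 3),
              0.3 * base[1L, ] + 0.7 * base[14L, ] + c(0, 5, 3),
              base[14L, ] + c(0, -2, 2))
  curve_pts <- bezier_points(cp, 7L, "arc_length")
  cfgs <- lapply(seq_len(n), function(i)
    landmark_config(rbind(base,
                          curve_pts + matrix(rnorm(21L, 0, jitter), 7L, 3L)),
                    specimen_id = paste0("s", i),
                    roles = c(rep("anatomical", 15L),
                              rep("curve_semilandmark", 7L))))
  list(cfgs = cfgs, curve = curve_definition(16:22), base = base,
       curve_pts = curve_pts)
}

test_that("a specimen identical to the reference does not slide", {
  cs <- make_curve_sample(n = 1L, jitter = 0)
  ref <- cs$cfgs[[1L]]$coords
  out <- slide_semilandmarks(cs$cfgs, list(cs$curve), iterations = 3L,
                             reference = ref)
  expect_equal(out$sample[[1L]]$coords, ref, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("sliding matches a dense line-search oracle for one point", {
  cs <- make_curve_sample(n = 1L, jitter = 0.5, seed = 43L)
  ref <- rbind(cs$base, cs$curve_pts)
  cfg <- cs$cfgs[[1L]]
  # oracle: move only landmark 19 (a middle semilandmark) along its
  # central-difference tangent, refitting the full TPS at each step
  Y0 <- cfg$coords
  d <- Y0[20L, ] - Y0[18L, ]
  d <- d / sqrt(sum(d^2))
  energy_at <- function(t) {
    Y <- Y0
    Y[19L, ] <- Y0[19L, ] + t * d
    tps_fit(ref, Y)$bending_energy
  }
  ts <- seq(-3, 3, length.out = 4001L)
  es <- vapply(ts, energy_at, 1.0)
  t_star <- ts[which.min(es)]
  opt <- stats::optimize(energy_at, c(t_star - 0.01, t_star + 0.01),
                         tol = 1e-10)
  # package: the analytic per-point minimizer along the same tangent
  B <- retromorph:::bending_energy_matrix(ref)
  g <- as.vector(B[19L, ] %*% Y0)
  t_pkg <- -sum(d * g) / B[19L, 19L]
  expect_equal(t_pkg, opt$minimum, tolerance = 1e-6)
})

test_that("sliding energy is non-increasing against a fixed reference", {
  cs <- make_curve_sample(n = 4L, jitter = 0.5, seed = 44L)
  ref <- rbind(cs$base, cs$curve_pts)
  out <- slide_semilandmarks(cs$cfgs, list(cs$curve), iterations = 5L,
                             reference = ref)
  for (i in 1:4)
    expect_true(all(diff(out$energy[, i]) <= 1e-9))
})

test_that("fixed landmarks and curve endpoints never move", {
  cs <- make_curve_sample(n = 3L, jitter = 0.6, seed = 45L)
  out <- slide_semilandmarks(cs$cfgs, list(cs$curve), iterations = 3L)
  for (i in 1:3) {
    expect_equal(out$sample[[i]]$coords[1:15, ], cs$cfgs[[i]]$coords[1:15, ],
                 tolerance = 1e-12)
    expect_equal(out$sample[[i]]$coords[c(16L, 22L), ],
                 cs$cfgs[[i]]$coords[c(16L, 22L), ], tolerance = 1e-12)
  }
  expect_error(curve_definition(1:2), "at least 3")
})

test_that("missing landmarks are recovered through the reference TPS", {
  tm <- make_template()
  # identity case: the target is the reference itself with one landmark cut
  cfg <- tm$config
  cfg$coords[5L, ] <- NA
  cfg$missing[5L] <- TRUE
  est <- estimate_missing_tps(cfg, list(tm$config))
  expect_lt(max(abs(est$coords[5L, ] - tm$config$coords[5L, ])), 1e-8)
  expect_false(any(est$missing))
  expect_false(est$sliding[5L])
  expect_identical(attr(est, "estimated"), 5L)
  # exact TPS image of the reference: recovery to 1e-6
  set.seed(46)
  ref <- tm$config$coords
  warp <- tps_fit(ref[seq(1, 33, by = 2), ],
                  ref[seq(1, 33, by = 2), ] +
                    matrix(rnorm(51L, 0, 2), 17L, 3L))
  img <- tps_apply(warp, ref)
  cfg2 <- landmark_config(img)
  cfg2$coords[10L, ] <- NA
  cfg2$missing[10L] <- TRUE
  est2 <- estimate_missing_tps(cfg2, list(tm$config))
  expect_lt(max(abs(est2$coords[10L, ] - img[10L, ])), 1e-6)
  # no missing landmarks: identity
  expect_identical(estimate_missing_tps(tm$config, list(tm$config)),
                   tm$config)
})

test_that("missing-landmark estimation is rigid-equivariant and accurate", {
  set.seed(47)
  tm <- make_template()
  ref <- tm$config$coords
  # equivariance: rigidly moving the target moves the estimate identically
  target <- ref + matrix(rnorm(99L, 0, 1), 33L, 3L)
  cfg <- landmark_config(target)
  cfg$coords[7L, ] <- NA; cfg$missing[7L] <- TRUE
  est <- estimate_missing_tps(cfg, list(tm$config))
  R <- random_rotation(); tr <- rnorm(3L)
  cfg_m <- landmark_config(target %*% R +
                             matrix(tr, 33L, 3L, byrow = TRUE))
  cfg_m$coords[7L, ] <- NA; cfg_m$missing[7L] <- TRUE
  est_m <- estimate_missing_tps(cfg_m, list(tm$config))
  expect_equal(est_m$coords[7L, ],
               as.vector(est$coords[7L, ] %*% R + tr), tolerance = 1e-6)
  # leave-one-out recovery under noise sd sigma stays within 3 sigma RMSE
  sigma <- 0.5
  errs <- vapply(1:20, function(r) {
    tgt <- ref + matrix(rnorm(99L, 0, sigma), 33L, 3L)
    j <- sample(33L, 1L)
    cc <- landmark_config(tgt)
    cc$coords[j, ] <- NA; cc$missing[j] <- TRUE
    ee <- estimate_missing_tps(cc, list(tm$config))
    sqrt(sum((ee$coords[j, ] - tgt[j, ])^2))
  }, 1.0)
  expect_lt(sqrt(mean(errs^2)), 3 * sigma * sqrt(3))
  # too few anchors
  cc <- landmark_config(ref)
  cc$coords[1:30, ] <- NA; cc$missing[1:30] <- TRUE
  expect_error(estimate_missing_tps(cc, list(tm$config)), "at least 4")
})
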