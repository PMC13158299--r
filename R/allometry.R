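#' Homogeneity-of-slopes test by vector correlation
#'
#' Fits a separate multivariate regression of shape on size within each
#' group and measures the angle between the two group slope vectors; the
#' vector correlation is the cosine of that angle.  Significance is assessed
#' by randomizing the residuals of the common-slope (parallel) model: under
#' the null of parallel slopes the observed angle should be typical of the
#' permutation distribution of angles.
#'
#' @param Y n x p shape matrix.
#' @param size numeric length-n size vector (mm).
#' @param group two-level factor.
#' @param n_perm number of permutations (default 999).
#' @param seed optional integer seed.
#' @return object of class `slope_test` with `angle_deg`,
#'   `vector_correlation` (= cos(angle)), `Z`, `p` and the permuted angles.
#' @export
slope_homogeneity_test <- function(Y, size, group, n_perm = 999L,
                                   seed = NULL) {
  Y <- as.matrix(Y)
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2L) stop("exactly two groups are required")
  if (any(table(group) < 3L))
    stop("each group needs at least 3 specimens to estimate a slope")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(Y)

  slope_angle <- function(Ym) {
    b <- lapply(levels(group), function(g) {
      i <- group == g
      stats::lm.fit(cbind(1, size[i]), Ym[i, , drop = FALSE])$coefficients[2L, ]
    })
    vc <- sum(b[[1L]] * b[[2L]]) /
      sqrt(sum(b[[1L]]^2) * sum(b[[2L]]^2))
    vc <- min(1, max(-1, vc))
    c(angle = acos(vc) * 180 / pi, vc = vc)
  }
  obs <- slope_angle(Y)
  # common-slope (parallel) null model: shape ~ size + group
  Xc <- stats::model.matrix(~ size + group)
  fitc <- stats::lm.fit(Xc, Y)
  fit_vals <- Xc %*% fitc$coefficients
  resid_c <- Y - fit_vals
  ang_p <- vapply(seq_len(n_perm), function(j) {
    Yp <- fit_vals + resid_c[sample.int(n), , drop = FALSE]
    slope_angle(Yp)[1L]
  }, 1.0)
  p <- (sum(ang_p >= obs[1L] - 1e-12) + 1) / (n_perm + 1)
  Z <- (obs[1L] - mean(ang_p)) / stats::sd(ang_p)
  structure(list(angle_deg = unname(obs[1L]),
                 vector_correlation = unname(obs[2L]),
                 Z = Z, p = p, perm_angles = ang_p),
            class = "slope_test")
}

#' @export
print.slope_test <- function(x, ...) {
  cat(sprintf(
    "Slope homogeneity: angle %.2f deg (r = %.3f), Z = %.2f, p = %.4g\n",
    x$angle_deg, x$vector_correlation, x$Z, x$p))
  invisible(x)
}

#' Spatial (geometric) median by Weiszfeld iteration
#'
#' @param X n x p matrix of points.
#' @param tol convergence tolerance; @param max_iter iteration cap.
#' @return length-p numeric vector minimizing the summed Euclidean distances.
#' @export
spatial_median <- function(X, tol = 1e-10, max_iter = 500L) {
  X <- as.matrix(X)
  m <- colMeans(X)
  for (it in seq_len(max_iter)) {
    d <- sqrt(rowSums(sweep(X, 2L, m)^2))
    if (any(d < 1e-12)) d <- pmax(d, 1e-12)
    w <- 1 / d
    m_new <- colSums(X * w) / sum(w)
    if (sqrt(sum((m_new - m)^2)) < tol) return(m_new)
    m <- m_new
  }
  m
}

#' Multivariate homogeneity of group dispersions
#'
#' Tests whether groups differ in multivariate dispersion: the Euclidean
#' distance matrix of the data is embedded by principal coordinates, each
#' specimen's distance to its group spatial (geometric) median is computed
#' (Weiszfeld iteration), and the one-way F statistic on those distances is
#' evaluated against group-label permutations.
#'
#' @param Y n x p data matrix (Euclidean distances are used).
#' @param groups grouping factor.
#' @param n_perm number of permutations (default 999).
#' @param seed optional integer seed.
#' @return list with `F`, `p`, `distances` (per specimen, to its group
#'   median), `medians` (per group, in the embedding coordinates).
#' @export
dispersion_homogeneity <- function(Y, groups, n_perm = 999L, seed = NULL) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2L) stop("at least 2 groups are required")
  if (any(table(groups) < 2L)) stop("every group needs at least 2 members")
  if (!is.null(seed)) set.seed(seed)
  Y <- as.matrix(Y)
  n <- nrow(Y)
  # principal-coordinate embedding of the Euclidean distance matrix (an
  # isometry here; kept so the test is defined by distances, not raw axes)
  mds <- stats::cmdscale(stats::dist(Y), k = min(n - 1L, ncol(Y)),
                         eig = TRUE)
  E <- mds$points[, mds$eig[seq_len(ncol(mds$points))] > 1e-8 * max(mds$eig),
                  drop = FALSE]
  disp_F <- function(g) {
    d <- numeric(n)
    for (lev in levels(g)) {
      i <- g == lev
      m <- spatial_median(E[i, , drop = FALSE], tol = 1e-12)
      d[i] <- sqrt(rowSums(sweep(E[i, , drop = FALSE], 2L, m)^2))
    }
    k <- nlevels(g)
    gm <- tapply(d, g, mean)
    ssb <- sum(table(g) * (gm - mean(d))^2)
    ssw <- sum((d - gm[g])^2)
    list(F = (ssb / (k - 1L)) / (ssw / (n - k)), d = d)
  }
  obs <- disp_F(groups)
  Fp <- vapply(seq_len(n_perm), function(j)
    disp_F(groups[sample.int(n)])$F, 1.0)
  p <- (sum(Fp >= obs$F - 1e-12) + 1) / (n_perm + 1)
  medians <- lapply(stats::setNames(levels(groups), levels(groups)),
                    function(lev)
                      spatial_median(E[groups == lev, , drop = FALSE],
                                     tol = 1e-12))
  list(F = obs$F, p = p, distances = obs$d, medians = medians)
}

#' Kendall's rank correlation (tau-b) with permutation-free p
#'
#' Tie-corrected tau-b from explicit concordance counts; the two-tailed p
#' comes from exact enumeration of all orderings for n <= 8 (no ties) and
#' from the normal approximation with tie correction otherwise.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with `tau`, `p`, `n`.
#' @export
kendall_tau_test <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y differ in length")
  if (n < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: tau is undefined")
  conc_disc <- function(x, y) {
    C <- 0L; D <- 0L
    for (i in seq_len(n - 1L))
      for (j in (i + 1L):n) {
        s <- sign(x[j] - x[i]) * sign(y[j] - y[i])
        if (s > 0) C <- C + 1L else if (s < 0) D <- D + 1L
      }
    c(C, D)
  }
  cd <- conc_disc(x, y)
  n0 <- n * (n - 1) / 2
  tx <- table(x); ty <- table(y)
  n1 <- sum(tx * (tx - 1) / 2)
  n2 <- sum(ty * (ty - 1) / 2)
  tau <- (cd[1L] - cd[2L]) / sqrt((n0 - n1) * (n0 - n2))
  has_ties <- n1 > 0 || n2 > 0
  if (n <= 8L && !has_ties) {
    # exact null distribution of tau by enumeration of all rank orderings
    perms <- all_permutations(n)
    taus <- apply(perms, 1L, function(p) {
      cdp <- 0L
      for (i in seq_len(n - 1L))
        for (j in (i + 1L):n)
          cdp <- cdp + sign(p[j] - p[i])
      cdp / n0
    })
    p <- mean(abs(taus) >= abs(tau) - 1e-12)
  } else {
    # normal approximation with tie correction (tau-b variance)
    v0 <- n * (n - 1) * (2 * n + 5)
    vt <- sum(tx * (tx - 1) * (2 * tx + 5))
    vu <- sum(ty * (ty - 1) * (2 * ty + 5))
    v1 <- sum(tx * (tx - 1)) * sum(ty * (ty - 1)) / (2 * n * (n - 1))
    v2 <- sum(tx * (tx - 1) * (tx - 2)) * sum(ty * (ty - 1) * (ty - 2)) /
      (9 * n * (n - 1) * (n - 2))
    var_s <- (v0 - vt - vu) / 18 + v1 + v2
    z <- (cd[1L] - cd[2L]) / sqrt(var_s)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(tau = tau, p = min(1, p), n = n)
}

# all permutations of 1..n (n small)
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, 0L, n)
  for (i in seq_len(n)) {
    block <- cbind(i, sub + (sub >= i))
    out <- rbind(out, block)
  }
  out
}

#' Variance inflation factor and tolerance of size on group
#'
#' Collinearity diagnostics between the continuous size predictor and the
#' group factor: VIF = 1 / (1 - R^2) of size regressed on the group
#' indicators; tolerance is its reciprocal.
#'
#' @param size numeric vector; @param group factor with >= 2 levels.
#' @return list with `vif`, `tolerance`, `r_squared`.
#' @export
vif_tolerance <- function(size, group) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) < 2L) stop("group needs at least 2 levels")
  fit <- stats::lm.fit(stats::model.matrix(~ group), size)
  r2 <- 1 - sum(fit$residuals^2) / sum((size - mean(size))^2)
  if (r2 >= 1 - 1e-12) stop("perfect separation: VIF is infinite")
  list(vif = 1 / (1 - r2), tolerance = 1 - r2, r_squared = r2)
}

#' Predicted mean shapes at a fixed size
#'
#' Least-squares group mean shapes predicted from a fitted common-allometry
#' model at a constant centroid size (typically the sample mean CS), with
#' permutation-based 95% uncertainty ellipses: full-model residuals are
#' randomized, coefficients refitted, and the replicate predictions
#' projected onto the PCA of the predicted means.
#'
#' @param fit an [rrpp_lm] fit whose model contains `size` and a group term.
#' @param fixed_size the size at which to predict (scalar).
#' @param size_var,group_var names of the size and group variables in the
#'   model data (defaults `"size"`, `"group"`).
#' @param n_perm permutation replicates for the ellipses (default 499).
#' @param conf ellipse coverage (default 0.95).
#' @param seed optional integer seed.
#' @return object of class `shape_prediction`: `predicted` (group x p),
#'   `perm_scores` (replicate predictions on the first two PCs, per group),
#'   `ellipses` (per group: center, covariance, radius), `pca` (basis).
#' @export
predict_shapes <- function(fit, fixed_size, size_var = "size",
                           group_var = "group", n_perm = 499L, conf = 0.95,
                           seed = NULL) {
  stopifnot(inherits(fit, "rrpp_fit"))
  if (!is.null(seed)) set.seed(seed)
  dat <- fit$data
  grp <- droplevels(as.factor(dat[[group_var]]))
  obs_range <- range(dat[[size_var]])
  if (fixed_size < obs_range[1L] || fixed_size > obs_range[2L])
    warning("predicting outside the observed size range (extrapolation)")
  newdata <- stats::setNames(
    data.frame(rep(fixed_size, nlevels(grp)), levels(grp),
               stringsAsFactors = FALSE),
    c(size_var, group_var))
  newdata[[group_var]] <- factor(newdata[[group_var]], levels = levels(grp))
  Xnew <- stats::model.matrix(fit$terms, newdata,
                              contrasts.arg = fit$contrasts_arg)
  pred <- Xnew %*% fit$coefficients
  rownames(pred) <- levels(grp)
  # permutation replicates of the predicted means
  n <- nrow(fit$Y)
  qrX <- qr(fit$X)
  reps <- array(NA_real_, c(nlevels(grp), ncol(fit$Y), n_perm))
  for (j in seq_len(n_perm)) {
    Yp <- fit$fitted + fit$residuals[sample.int(n), , drop = FALSE]
    Bp <- qr.coef(qrX, Yp)
    reps[, , j] <- Xnew %*% Bp
  }
  # project replicates with the PCA of the replicate predicted-mean cloud
  cloud <- do.call(rbind, lapply(seq_len(nlevels(grp)), function(g)
    t(reps[g, , ])))
  pc <- stats::prcomp(cloud, center = TRUE, scale. = FALSE)
  d2 <- min(2L, ncol(pc$rotation))
  basis <- pc$rotation[, seq_len(d2), drop = FALSE]
  perm_scores <- lapply(seq_len(nlevels(grp)), function(g)
    sweep(t(reps[g, , ]), 2L, pc$center) %*% basis)
  names(perm_scores) <- levels(grp)
  ellipses <- lapply(perm_scores, function(s) {
    ctr <- colMeans(s)
    S <- stats::cov(s)
    list(center = ctr, cov = S,
         radius2 = stats::qchisq(conf, df = ncol(s)))
  })
  structure(list(predicted = pred, perm_scores = perm_scores,
                 ellipses = ellipses, basis = basis, center = pc$center,
                 fixed_size = fixed_size, conf = conf),
            class = "shape_prediction")
}

#' Regression scores of a shape-on-size model
#'
#' Projection of the centered shape data onto the normalized size-coefficient
#' vector: the shape variable associated with the shape changes predicted by
#' the regression, including residual variation in that direction.
#'
#' @param fit an [rrpp_lm] fit containing a `size` term.
#' @param size_var name of the size variable (default `"size"`).
#' @return numeric vector of n scores.
#' @export
regression_scores <- function(fit, size_var = "size") {
  stopifnot(inherits(fit, "rrpp_fit"))
  cn <- rownames(fit$coefficients)
  i <- which(cn == size_var)
  if (length(i) != 1L) stop("no '", size_var, "' coefficient in the model")
  b <- fit$coefficients[i, ]
  nb <- sqrt(sum(b^2))
  if (nb < 1e-12) stop("size coefficient is (numerically) zero")
  Yc <- sweep(fit$Y, 2L, colMeans(fit$Y))
  as.vector(Yc %*% (b / nb))
}

#' PCA of model-fitted values
#'
#' Decomposes the model-predicted component of shape variation; with q
#' linearly independent predictor columns the fitted values have at most q
#' nonzero components.
#'
#' @param fit an [rrpp_lm] fit.
#' @return a [shape_pca] of the fitted values.
#' @export
fitted_value_pca <- function(fit) {
  stopifnot(inherits(fit, "rrpp_fit"))
  shape_pca(fit$fitted)
}

#' Size-by-group diagnostics
#'
#' Bundles the standard diagnostics for comparing a size variable between
#' two groups: a Wilcoxon-Mann-Whitney test with a Monte-Carlo p-value from
#' label permutation of the rank-sum statistic, the rank-biserial effect
#' size, Bartlett's test of equal variances and per-group Shapiro-Wilk
#' normality tests.
#'
#' @param size numeric vector; @param group two-level factor.
#' @param n_mc Monte-Carlo permutations (default 9999).
#' @param seed optional integer seed.
#' @return list with `wilcoxon_p_mc`, `wilcoxon_W`, `rank_effect_size`,
#'   `bartlett_p`, `shapiro_p` (named per group).
#' @export
size_group_diagnostics <- function(size, group, n_mc = 9999L, seed = NULL) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2L) stop("exactly two groups are required")
  if (any(table(group) < 3L)) stop("need at least 3 per group")
  if (!is.null(seed)) set.seed(seed)
  g1 <- levels(group)[1L]
  n1 <- sum(group == g1); n2 <- sum(group != g1)
  r <- rank(size)
  W_obs <- sum(r[group == g1]) - n1 * (n1 + 1) / 2
  Wp <- vapply(seq_len(n_mc), function(j) {
    gp <- sample(group)
    sum(r[gp == g1]) - n1 * (n1 + 1) / 2
  }, 1.0)
  dev_obs <- abs(W_obs - n1 * n2 / 2)
  p_mc <- (sum(abs(Wp - n1 * n2 / 2) >= dev_obs - 1e-12) + 1) / (n_mc + 1)
  rbs <- 2 * W_obs / (n1 * n2) - 1     # rank-biserial correlation
  bart <- stats::bartlett.test(size, group)$p.value
  shap <- vapply(levels(group), function(g)
    stats::shapiro.test(size[group == g])$p.value, 1.0)
  list(wilcoxon_p_mc = p_mc, wilcoxon_W = W_obs, rank_effect_size = rbs,
       bartlett_p = bart, shapiro_p = shap)
}
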