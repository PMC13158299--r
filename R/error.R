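#' Set of repeated digitization trials
#'
#' Bundles landmark configurations indexed by specimen and trial for the
#' measurement-error protocol; every specimen must have the same number of
#' trials and the same landmark scheme.
#'
#' @param configs list of [landmark_config]s (or k x 3 matrices).
#' @param specimen character/factor of length `length(configs)`.
#' @param trial character/factor of length `length(configs)`.
#' @param resolution optional per-specimen resolution tag.
#' @return object of class `trial_set`.
#' @export
trial_set <- function(configs, specimen, trial, resolution = NULL) {
  n <- length(configs)
  specimen <- as.factor(specimen)
  trial <- as.factor(trial)
  if (length(specimen) != n || length(trial) != n)
    stop("specimen/trial labels must match the number of configurations")
  ks <- vapply(configs, function(x) nrow(lm_coords(x)), 1L)
  if (length(unique(ks)) != 1L)
    stop("all trials must share the same landmark scheme")
  tt <- table(specimen, trial)
  if (length(unique(rowSums(tt))) != 1L)
    stop("every specimen must have the same number of trials")
  structure(list(configs = configs, specimen = specimen, trial = trial,
                 resolution = resolution, k = ks[1L]),
            class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  cat(sprintf("Trial set: %d specimens x %d trials, %d landmarks\n",
              nlevels(x$specimen), nlevels(x$trial), x$k))
  invisible(x)
}

#' Per-landmark digitization error summary
#'
#' For each landmark and specimen, the Euclidean distances of every trial's
#' landmark to its across-trial mean position are computed and summarized as
#' a standard deviation, in mm and as a percentage of the specimen's mean
#' centroid size.  In `space = "boas"` the trials are first Procrustes
#' superimposed and returned to their original size (registration without
#' scaling), so orientation differences between trials are removed before
#' the distances are taken.  Landmarks exceeding the conventional 1 mm and
#' 2 mm SD thresholds are flagged.
#'
#' @param trials a [trial_set].
#' @param space `"raw"` (default) or `"boas"`.
#' @return data.frame with columns `specimen`, `landmark`, `sd_mm`,
#'   `sd_percent_cs`, `above_1mm`, `above_2mm`.
#' @export
landmark_error_summary <- function(trials, space = c("raw", "boas")) {
  space <- match.arg(space)
  stopifnot(inherits(trials, "trial_set"))
  if (nlevels(trials$trial) < 2L) stop("need at least 2 trials")
  out <- NULL
  for (sp in levels(trials$specimen)) {
    sel <- which(trials$specimen == sp)
    mats <- lapply(trials$configs[sel], lm_coords)
    if (space == "boas") {
      al <- gpa(mats, scale_mode = "boas")
      mats <- lapply(seq_along(sel), function(i) al$rotated[, , i])
    }
    cs_mean <- mean(vapply(mats, centroid_size, 1.0))
    mean_cfg <- Reduce(`+`, mats) / length(mats)
    dev <- vapply(mats, function(m)
      sqrt(rowSums((m - mean_cfg)^2)), numeric(trials$k))
    sds <- apply(dev, 1L, stats::sd)
    out <- rbind(out, data.frame(
      specimen = sp,
      landmark = rownames(lm_coords(trials$configs[[sel[1L]]])) %||%
        paste0("L", seq_len(trials$k)),
      sd_mm = sds,
      sd_percent_cs = 100 * sds / cs_mean,
      above_1mm = sds > 1,
      above_2mm = sds > 2,
      row.names = NULL))
  }
  out
}

#' Pairwise Riemannian distances between trials
#'
#' @param trials a [trial_set].
#' @return named list of symmetric zero-diagonal trial-by-trial Riemannian
#'   distance matrices, one per specimen.
#' @export
trial_riemannian_distances <- function(trials) {
  stopifnot(inherits(trials, "trial_set"))
  lapply(stats::setNames(levels(trials$specimen),
                         levels(trials$specimen)), function(sp) {
    sel <- which(trials$specimen == sp)
    nt <- length(sel)
    rd <- matrix(0, nt, nt,
                 dimnames = list(as.character(trials$trial[sel]),
                                 as.character(trials$trial[sel])))
    for (i in seq_len(nt - 1L))
      for (j in (i + 1L):nt)
        rd[i, j] <- rd[j, i] <- riemannian_distance(
          trials$configs[[sel[i]]], trials$configs[[sel[j]]])
    rd
  })
}

#' Repeatability from two-way Procrustes ANOVA
#'
#' Superimposes all trial configurations together (GPA, unit size), runs a
#' two-way residual-randomization Procrustes ANOVA of the tangent
#' coordinates on specimen and trial (Type II SS), and derives repeatability
#' as an intraclass correlation coefficient from the mean squares:
#' `ICC = (MS_specimen - MS_residual) / (MS_specimen + (k_trials - 1) *
#' MS_residual)`, clamped to `[0, 1]`.  Measurement error is
#' `ME% = (1 - ICC) * 100`.  Trials can optionally be symmetrized first to
#' extract their symmetric component.
#'
#' @param trials a [trial_set] with >= 2 specimens and >= 2 trials.
#' @param pairing optional [pairing_table]; when given, every trial is
#'   symmetrized by reflected relabeling before superimposition.
#' @param n_perm permutations for the ANOVA (default 999).
#' @param seed optional integer seed.
#' @return object of class `error_summary` with `icc`, `me_percent`,
#'   `anova` (the `rrpp_fit`), `clamped` (logical).
#' @export
procrustes_anova_icc <- function(trials, pairing = NULL, n_perm = 999L,
                                 seed = NULL) {
  stopifnot(inherits(trials, "trial_set"))
  if (nlevels(trials$specimen) < 2L || nlevels(trials$trial) < 2L)
    stop("need at least 2 specimens and 2 trials")
  configs <- trials$configs
  if (!is.null(pairing))
    configs <- lapply(configs, symmetrize_reflect_relabel, pairing = pairing)
  al <- gpa(configs)
  dat <- data.frame(specimen = trials$specimen, trial = trials$trial)
  fit <- rrpp_lm(~ specimen + trial, dat, al$tangent, ss_type = "II",
                 n_perm = n_perm, seed = seed)
  ms_spec <- fit$aov_table["specimen", "MS"]
  ms_res <- fit$aov_table["Residuals", "MS"]
  k_trials <- nlevels(trials$trial)
  icc_raw <- (ms_spec - ms_res) / (ms_spec + (k_trials - 1) * ms_res)
  clamped <- icc_raw < 0 || icc_raw > 1
  if (icc_raw < 0)
    warning("negative variance component; ICC clamped to 0")
  icc <- min(1, max(0, icc_raw))
  structure(list(icc = icc, me_percent = (1 - icc) * 100, anova = fit,
                 icc_raw = icc_raw, clamped = clamped,
                 k_trials = k_trials),
            class = "error_summary")
}

#' @export
print.error_summary <- function(x, ...) {
  cat(sprintf("Procrustes ANOVA repeatability: ICC = %.4f, ME = %.2f%%\n",
              x$icc, x$me_percent))
  invisible(x)
}

#' Blocked permutational MANOVA
#'
#' Permutational MANOVA (Type I SS) of a multivariate response on one
#' factor, with permutations restricted to shuffle observations only within
#' the given blocks (non-exchangeable strata).  Stands on `vegan::adonis2`
#' with a within-block permutation scheme from the permute package.
#'
#' @param Y n x p response matrix (Euclidean distances are used).
#' @param factor_ grouping factor under test.
#' @param blocks factor partitioning the observations; every block needs
#'   more than one observation.
#' @param n_perm number of permutations (default 999).
#' @param seed optional integer seed.
#' @return list with `p`, `F`, `aov_table` (the adonis2 table).
#' @export
blocked_manova <- function(Y, factor_, blocks, n_perm = 999L, seed = NULL) {
  factor_ <- as.factor(factor_)
  blocks <- as.factor(blocks)
  if (any(table(blocks) < 2L))
    stop("every block needs at least 2 observations")
  if (!is.null(seed)) set.seed(seed)
  ctrl <- permute::how(blocks = blocks, nperm = n_perm)
  d <- stats::dist(as.matrix(Y))
  dat <- data.frame(f = factor_)
  res <- vegan::adonis2(d ~ f, data = dat, permutations = ctrl,
                        by = "terms")
  list(p = res$`Pr(>F)`[1L], F = res$F[1L], aov_table = res)
}
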