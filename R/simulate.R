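#' Build a bilaterally symmetric template configuration
#'
#' Constructs a smooth, perfectly symmetric 3D landmark template: paired
#' landmarks mirrored across the x = 0 midsagittal plane on a smooth
#' ellipsoid-like surface, midline landmarks on the plane itself.  The
#' default scheme of 14 pairs + 5 midline points emits 33 landmarks,
#' mirroring a facial anatomical-landmark configuration.  The template is
#' deterministic for given arguments; optional jitter (seeded) roughens the
#' surface while preserving exact symmetry.
#'
#' @param k_pairs number of bilateral pairs (>= 4; default 14).
#' @param k_midline number of midline landmarks (default 5).
#' @param scale overall size factor: the template is scaled to centroid
#'   size `scale` (default 100, nominally mm).
#' @param jitter_sd symmetric surface jitter as a fraction of `scale`
#'   (default 0).
#' @param seed seed for the jitter.
#' @return list with `config` (a [landmark_config]) and `pairing`
#'   (a [pairing_table]).
#' @export
make_template <- function(k_pairs = 14L, k_midline = 5L, scale = 100,
                          jitter_sd = 0, seed = 1L) {
  if (k_pairs < 4L) stop("need at least 4 bilateral pairs")
  # paired points: two interleaved arcs on a smooth ovoid, x > 0 side
  t_par <- seq(0.15, 0.85, length.out = k_pairs)
  right <- cbind(0.35 + 0.25 * sin(pi * t_par) * cos(2.5 * pi * t_par),
                 cos(pi * t_par),
                 0.55 * sin(pi * t_par) * sin(2.5 * pi * t_par) +
                   0.3 * t_par)
  if (jitter_sd > 0) {
    set.seed(seed)
    right <- right + matrix(stats::rnorm(3 * k_pairs, 0, jitter_sd),
                            ncol = 3L)
    right[, 1L] <- pmax(right[, 1L], 0.05)
  }
  left <- right
  left[, 1L] <- -left[, 1L]
  t_mid <- seq(0, 1, length.out = k_midline)
  midline <- cbind(0, 1.2 * cos(pi * t_mid), 0.8 * sin(pi * t_mid))
  coords <- rbind(left, right, midline)
  coords <- center_config(coords)
  coords <- coords * (scale / sqrt(sum(sweep(coords, 2, colMeans(coords))^2)))
  k <- nrow(coords)
  names <- c(paste0("P", seq_len(k_pairs), "_L"),
             paste0("P", seq_len(k_pairs), "_R"),
             paste0("M", seq_len(k_midline)))
  cfg <- landmark_config(coords, specimen_id = "template",
                         landmark_names = names)
  pt <- pairing_table(cbind(seq_len(k_pairs), k_pairs + seq_len(k_pairs)),
                      midline = 2L * k_pairs + seq_len(k_midline), k = k)
  list(config = cfg, pairing = pt)
}

# smooth, symmetry-respecting unit direction in configuration space,
# orthogonal to the similarity directions (translations, scaling) at the
# template; used to build slope/offset vectors
smooth_shape_direction <- function(template, seed) {
  set.seed(seed)
  k <- nrow(template)
  v <- matrix(stats::rnorm(3 * k), k, 3L)
  # smooth by averaging over nearest template neighbours
  d <- as.matrix(stats::dist(template))
  w <- exp(-(d / stats::median(d))^2)
  v <- w %*% v / rowSums(w)
  v <- center_config(v)                       # remove translation
  tpl <- center_config(template)
  v <- v - tpl * sum(v * tpl) / sum(tpl^2)    # remove pure scaling
  v / sqrt(sum(v^2))
}

#' Simulate a two-group allometric landmark sample
#'
#' Generates landmark configurations with the statistical structure the
#' allometry analysis assumes: a symmetric template, a common allometric
#' slope (shape change per mm of centroid size), a group mean offset, an
#' optional group-specific slope divergence (the second group's slope
#' rotated by a fixed angle), and iid Gaussian digitization noise.  Each
#' configuration is scaled to its drawn centroid size and placed in a
#' random orientation and position, so the full Procrustes pipeline is
#' exercised.  The defaults mirror an unbalanced two-genus comparative
#' design: 27 + 7 specimens across 12 species whose centroid-size ranges
#' partially overlap.
#'
#' @param template optional template from [make_template()] (list with
#'   `config` and `pairing`); default `make_template()`.
#' @param n_per_group integer vector of two group sizes (default c(27, 7)).
#' @param size_mean,size_sd per-group centroid-size means and SDs in mm
#'   (defaults c(95, 115) and c(8, 8): overlapping ranges).
#' @param slope_per_mm magnitude of the common allometric shape change per
#'   mm of CS, in units of unit-shape displacement (default 3.5e-3).
#' @param group_offset_mag magnitude of the group B mean shape offset
#'   (default 0.075).
#' @param divergence_angle_deg angle (degrees) by which group B's slope is
#'   rotated away from the common slope (default 0: parallel slopes).
#' @param noise_sd digitization noise SD in mm per coordinate (default 0.5).
#' @param n_species number of species labels spread over the two groups
#'   (default 12; group B receives 2 of them).
#' @param with_tree logical; attach a random ultrametric species tree
#'   (default TRUE).
#' @param seed integer seed (default 1).
#' @return object of class `simulated_dataset`: `configs` (list of
#'   [landmark_config]), `metadata` (genus/species/sex/dental_score/size),
#'   `true` (generating parameters incl. the slope/offset vectors),
#'   `template`, `pairing`, `tree` (Newick or NULL).
#' @export
simulate_allometric_sample <- function(template = NULL,
                                       n_per_group = c(27L, 7L),
                                       size_mean = c(95, 115),
                                       size_sd = c(8, 8),
                                       slope_per_mm = 3.5e-3,
                                       group_offset_mag = 0.075,
                                       divergence_angle_deg = 0,
                                       noise_sd = 0.5,
                                       n_species = 12L,
                                       with_tree = TRUE,
                                       seed = 1L) {
  if (any(size_sd < 0) || noise_sd < 0) stop("negative sd")
  if (is.null(template)) template <- make_template()
  tpl <- lm_coords(template$config)
  k <- nrow(tpl)
  cs0 <- centroid_size(tpl)
  set.seed(seed)
  slope_dir <- smooth_shape_direction(tpl, seed = seed + 101L)
  offset_dir <- smooth_shape_direction(tpl, seed = seed + 202L)
  offset_dir <- offset_dir - slope_dir * sum(offset_dir * slope_dir)
  offset_dir <- offset_dir / sqrt(sum(offset_dir^2))
  # slope for group B: common slope rotated toward an orthogonal direction
  orth_dir <- smooth_shape_direction(tpl, seed = seed + 303L)
  orth_dir <- orth_dir - slope_dir * sum(orth_dir * slope_dir)
  orth_dir <- orth_dir - offset_dir * sum(orth_dir * offset_dir)
  orth_dir <- orth_dir / sqrt(sum(orth_dir^2))
  th <- divergence_angle_deg * pi / 180
  slope_b <- cos(th) * slope_dir + sin(th) * orth_dir

  n <- sum(n_per_group)
  genus <- factor(rep(c("GenusA", "GenusB"), n_per_group))
  sizes <- c(stats::rnorm(n_per_group[1L], size_mean[1L], size_sd[1L]),
             stats::rnorm(n_per_group[2L], size_mean[2L], size_sd[2L]))
  sizes <- pmax(sizes, 10)
  sbar <- mean(sizes)
  n_sp_b <- max(1L, min(round(n_species * n_per_group[2L] / n), n_species - 1L))
  n_sp_a <- n_species - n_sp_b
  species <- character(n)
  species[genus == "GenusA"] <-
    paste0("A_sp", 1L + (seq_len(n_per_group[1L]) %% n_sp_a))
  species[genus == "GenusB"] <-
    paste0("B_sp", 1L + (seq_len(n_per_group[2L]) %% n_sp_b))
  sex <- sample(c("F", "M"), n, replace = TRUE)
  dental <- sample(1:5, n, replace = TRUE)

  configs <- vector("list", n)
  for (i in seq_len(n)) {
    sl <- if (genus[i] == "GenusA") slope_dir else slope_b
    shp <- tpl / cs0 +
      sl * slope_per_mm * (sizes[i] - sbar) +
      if (genus[i] == "GenusB") offset_dir * group_offset_mag else 0
    x <- shp * sizes[i]
    # random rigid motion
    q <- qr.Q(qr(matrix(stats::rnorm(9), 3L)))
    if (det(q) < 0) q[, 1L] <- -q[, 1L]
    x <- x %*% q
    x <- sweep(x, 2L, stats::rnorm(3L, 0, 50), `+`)
    x <- x + matrix(stats::rnorm(3L * k, 0, noise_sd), k, 3L)
    configs[[i]] <- landmark_config(
      x, specimen_id = sprintf("%s_%02d", genus[i], i),
      landmark_names = template$config$landmark_names)
  }
  metadata <- data.frame(specimen_id = vapply(configs, `[[`, "",
                                              "specimen_id"),
                         genus = genus, species = species, sex = sex,
                         dental_score = dental, true_size = sizes)
  tree <- if (with_tree)
    random_species_tree(unique(species), seed = seed + 404L) else NULL
  structure(list(configs = configs, metadata = metadata,
                 true = list(slope_dir = slope_dir, slope_b = slope_b,
                             offset_dir = offset_dir,
                             slope_per_mm = slope_per_mm,
                             group_offset_mag = group_offset_mag,
                             divergence_angle_deg = divergence_angle_deg,
                             noise_sd = noise_sd, sizes = sizes,
                             seed = seed),
                 template = template$config, pairing = template$pairing,
                 tree = tree),
            class = "simulated_dataset")
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf("Simulated dataset: %d specimens (%s), %d landmarks\n",
              length(x$configs),
              paste(table(x$metadata$genus), collapse = " + "),
              nrow(lm_coords(x$configs[[1L]]))))
  invisible(x)
}

#' Apply a plastic deformation to a configuration or mesh
#'
#' Emulates post-mortem plastic deformation.  `"affine_shear"` applies a
#' global mirror-odd shear (displacement of the midline-normal x axis by a
#' transverse direction, the component of an affine deformation that
#' bilateral retrodeformation can recover exactly); `"unilateral"` blends
#' identity with that shear through a logistic ramp across the midline so
#' that one side deforms much more than the other.
#'
#' @param x a [landmark_config], k x 3 matrix, or [triangle_mesh].
#' @param mode `"affine_shear"` or `"unilateral"`.
#' @param magnitude shear coefficient (0 = identity).
#' @param direction length-3 shear direction (default y axis); its x
#'   component is ignored.
#' @param side `"right"` (x > 0; default) or `"left"`: the side that
#'   deforms in unilateral mode.
#' @param ramp_scale logistic ramp width as a fraction of the configuration
#'   extent (default 0.2).
#' @return deformed copy of `x`; attributes `shear_matrix` and
#'   `ground_truth` (the input coordinates/vertices).
#' @export
apply_plastic_deformation <- function(x, mode = c("affine_shear",
                                                  "unilateral"),
                                      magnitude = 0.2,
                                      direction = c(0, 1, 0),
                                      side = c("right", "left"),
                                      ramp_scale = 0.2) {
  mode <- match.arg(mode)
  side <- match.arg(side)
  pts <- if (inherits(x, "triangle_mesh")) x$vertices else lm_coords(x)
  gt <- pts
  dvec <- as.numeric(direction)
  dvec[1L] <- 0
  nd <- sqrt(sum(dvec^2))
  if (nd == 0) stop("shear direction must have a transverse component")
  dvec <- dvec / nd
  S <- diag(3)
  S[1L, 2L:3L] <- magnitude * dvec[2L:3L]   # x' = x + m * (d . (y,z))
  if (abs(det(S)) < 1e-12) stop("magnitude produces a non-invertible map")
  sheared <- pts %*% t(S)
  if (mode == "affine_shear") {
    out_pts <- sheared
  } else {
    ext <- max(pts[, 1L]) - min(pts[, 1L])
    xx <- if (side == "right") pts[, 1L] else -pts[, 1L]
    w <- 1 / (1 + exp(-xx / (ramp_scale * ext)))
    out_pts <- pts + w * (sheared - pts)
  }
  out <- x
  if (inherits(x, "triangle_mesh")) out$vertices <- out_pts
  else if (inherits(x, "landmark_config")) out$coords[] <- out_pts
  else out <- out_pts
  attr(out, "shear_matrix") <- S
  attr(out, "ground_truth") <- gt
  out
}

#' Simulate repeated digitization trials
#'
#' Each trial is the input configuration plus iid Gaussian jitter; an
#' optional per-specimen resolution multiplier scales the noise (emulating
#' surface models of decreasing resolution).  The default design of 3
#' specimens x 4 trials mirrors a standard intra-observer error protocol.
#'
#' @param configs list of complete [landmark_config]s (the "specimens").
#' @param noise_sd digitization noise SD in mm.
#' @param n_trials trials per specimen (default 4).
#' @param resolution_factor numeric vector (one per specimen) multiplying
#'   the noise (default 1).
#' @param seed integer seed.
#' @return a [trial_set].
#' @export
simulate_digitization_trials <- function(configs, noise_sd = 0.25,
                                         n_trials = 4L,
                                         resolution_factor = 1,
                                         seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (inherits(configs, "landmark_config")) configs <- list(configs)
  ns <- length(configs)
  resolution_factor <- rep_len(resolution_factor, ns)
  set.seed(seed)
  out <- list(); spec <- character(0); tri <- character(0)
  for (i in seq_len(ns)) {
    base <- lm_coords(configs[[i]])
    id <- if (inherits(configs[[i]], "landmark_config"))
      configs[[i]]$specimen_id else paste0("spec", i)
    for (t in seq_len(n_trials)) {
      jit <- matrix(stats::rnorm(length(base), 0,
                                 noise_sd * resolution_factor[i]),
                    nrow(base), 3L)
      out <- c(out, list(landmark_config(base + jit,
                                         specimen_id = id)))
      spec <- c(spec, id)
      tri <- c(tri, paste0("t", t))
    }
  }
  trial_set(out, spec, tri,
            resolution = stats::setNames(resolution_factor,
                                         vapply(configs, function(x)
                                           if (inherits(x, "landmark_config"))
                                             x$specimen_id else "",
                                           "")))
}

#' Simulate a reference set for hyperplane restoration
#'
#' Draws reference configurations on a low-dimensional linear shape manifold
#' around the template, then builds a target as a manifold (hull) point plus
#' a deformation orthogonal (in configuration space) to the hull directions,
#' the similarity directions and — to second order — the superimposition
#' itself, so that hyperplane restoration can recover the true target
#' essentially exactly.  Mirrors a three-reference restoration protocol.
#'
#' @param template template list from [make_template()].
#' @param n_refs number of references (default 3).
#' @param basis_dim dimension of the reference manifold
#'   (default `n_refs - 1`, the hull dimension).
#' @param ref_spread magnitude of reference dispersion on the manifold
#'   (unit-shape scale; default 0.03).
#' @param target_offset magnitude of the orthogonal deformation applied to
#'   the target (default 1e-5).
#' @param seed integer seed.
#' @return list with `references` (list of k x 3 matrices), `target`
#'   (deformed), `true_target` (the hull point), `pairing`.
#' @export
simulate_reference_set <- function(template = NULL, n_refs = 3L,
                                   basis_dim = NULL, ref_spread = 0.03,
                                   target_offset = 1e-5, seed = 1L) {
  if (is.null(template)) template <- make_template()
  if (is.null(basis_dim)) basis_dim <- n_refs - 1L
  if (basis_dim > n_refs - 1L)
    stop("basis_dim must be <= n_refs - 1")
  tpl <- preshape(lm_coords(template$config))
  k <- nrow(tpl)
  set.seed(seed)
  basis <- lapply(seq_len(basis_dim), function(j)
    smooth_shape_direction(tpl, seed = seed + 10L * j))
  refs <- lapply(seq_len(n_refs), function(i) {
    co <- stats::rnorm(basis_dim, 0, ref_spread)
    x <- tpl
    for (j in seq_len(basis_dim)) x <- x + co[j] * basis[[j]]
    x * 100
  })
  # true target: a point inside the reference hull
  wts <- stats::runif(n_refs)
  wts <- wts / sum(wts)
  true_target <- Reduce(`+`, Map(`*`, refs, wts))
  # orthogonal deformation: random direction purged of the hull directions,
  # translations, scaling and infinitesimal rotations at the target
  v <- matrix(stats::rnorm(3L * k), k, 3L)
  v <- center_config(v)
  tt <- center_config(true_target)
  span <- cbind(as.vector(tt),
                sapply(refs, function(r) as.vector(center_config(r) -
                                                     tt)),
                as.vector(tt %*% rbind(c(0, -1, 0), c(1, 0, 0),
                                       c(0, 0, 0))),
                as.vector(tt %*% rbind(c(0, 0, -1), c(0, 0, 0),
                                       c(1, 0, 0))),
                as.vector(tt %*% rbind(c(0, 0, 0), c(0, 0, -1),
                                       c(0, 1, 0))))
  q <- qr.Q(qr(span))
  vv <- as.vector(v)
  vv <- vv - q %*% crossprod(q, vv)
  vv <- vv / sqrt(sum(vv^2))
  target <- true_target + matrix(vv, k, 3L) * target_offset *
    centroid_size(true_target)
  list(references = refs, target = target, true_target = true_target,
       pairing = template$pairing)
}

#' Mirror a one-sided surface-semilandmark patch
#'
#' Reflects a left-side patch across the x = 0 midsagittal plane and stacks
#' original and mirror, doubling the point count (e.g. a 120-point left
#' patch becomes a 240-point bilateral patch).
#'
#' @param patch m x 3 matrix of points (one side).
#' @return 2m x 3 matrix: the input followed by its mirror image.
#' @export
mirror_surface_patch <- function(patch) {
  patch <- as.matrix(patch)
  m <- patch
  m[, 1L] <- -m[, 1L]
  rbind(patch, m)
}
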