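#' Curve definition for sliding semilandmarks
#'
#' @param indices ordered landmark indices along the curve.
#' @param fixed_endpoints logical; endpoints are treated as fixed anchors
#'   (default `TRUE`).
#' @return object of class `curve_definition`.
#' @export
curve_definition <- function(indices, fixed_endpoints = TRUE) {
  indices <- as.integer(indices)
  if (length(indices) < 3L) stop("a sliding curve needs at least 3 points")
  structure(list(indices = indices, fixed_endpoints = fixed_endpoints),
            class = "curve_definition")
}

# nearest point on a polyline (v: p x 3 vertices) to point x
project_to_polyline <- function(x, v) {
  best <- v[1L, ]
  bestd <- Inf
  for (i in seq_len(nrow(v) - 1L)) {
    a <- v[i, ]; b <- v[i + 1L, ]
    ab <- b - a
    tt <- sum((x - a) * ab) / max(sum(ab^2), 1e-30)
    tt <- min(1, max(0, tt))
    p <- a + tt * ab
    d <- sum((x - p)^2)
    if (d < bestd) { bestd <- d; best <- p }
  }
  best
}

# unit tangent directions along a polyline by central differences
polyline_tangents <- function(v) {
  p <- nrow(v)
  tang <- matrix(0, p, 3L)
  for (i in seq_len(p)) {
    a <- v[max(1L, i - 1L), ]
    b <- v[min(p, i + 1L), ]
    d <- b - a
    nd <- sqrt(sum(d^2))
    tang[i, ] <- if (nd > 0) d / nd else c(1, 0, 0)
  }
  tang
}

#' Slide curve semilandmarks by minimized bending energy
#'
#' Iteratively relaxes curve semilandmarks against the sample mean shape:
#' each sliding point moves along its local polyline tangent to the position
#' minimizing the bending energy of the thin-plate spline from the current
#' mean to the specimen, and is then projected back onto its polyline.  A
#' move is only accepted if it does not increase the specimen's bending
#' energy, so the energy sequence is non-increasing.  Fixed landmarks and
#' curve endpoints never move.
#'
#' @param sample list of [landmark_config] objects sharing a landmark scheme.
#' @param curves list of [curve_definition]s.
#' @param iterations number of relaxation sweeps (default 3).
#' @param reference `"mean"` (recompute the GPA mean between sweeps, the
#'   default) or a fixed k x 3 matrix to slide against.
#' @return list with `sample` (slid configurations) and `energy`
#'   (iterations x n matrix of bending energies after each sweep).
#' @export
slide_semilandmarks <- function(sample, curves, iterations = 3L,
                                reference = "mean") {
  if (inherits(sample, "landmark_config")) sample <- list(sample)
  stopifnot(length(sample) >= 1L)
  for (cv in curves) {
    if (!inherits(cv, "curve_definition")) stop("curves must be curve_definition objects")
  }
  n <- length(sample)
  k <- nrow(lm_coords(sample[[1L]]))
  slidable <- rep(FALSE, k)
  for (cv in curves) {
    idx <- cv$indices
    inner <- if (cv$fixed_endpoints) idx[-c(1L, length(idx))] else idx
    slidable[inner] <- TRUE
  }
  # sliding_allowed flags of the configs gate the curve-derived set
  if (inherits(sample[[1L]], "landmark_config"))
    slidable <- slidable & sample[[1L]]$sliding
  energy <- matrix(NA_real_, iterations, n)
  mats <- lapply(sample, lm_coords)
  for (it in seq_len(iterations)) {
    ref <- if (is.character(reference) && reference == "mean") {
      al <- gpa(mats)
      al$mean_shape * mean(vapply(mats, centroid_size, 1.0))
    } else as.matrix(reference)
    B <- bending_energy_matrix(ref)
    for (i in seq_len(n)) {
      Y <- mats[[i]]
      e_cur <- sum(diag(crossprod(Y, B %*% Y)))
      for (cv in curves) {
        idx <- cv$indices
        poly <- Y[idx, , drop = FALSE]
        tang <- polyline_tangents(poly)
        inner <- seq_along(idx)
        if (cv$fixed_endpoints) inner <- inner[-c(1L, length(idx))]
        for (jj in inner) {
          j <- idx[jj]
          if (!slidable[j]) next
          d <- tang[jj, ]
          g <- as.vector(B[j, ] %*% Y)        # gradient row (B Y)[j, ]
          tstar <- -sum(d * g) / B[j, j]
          if (!is.finite(tstar)) next
          cand <- Y[j, ] + tstar * d
          cand <- project_to_polyline(cand, poly)
          Ynew <- Y
          Ynew[j, ] <- cand
          e_new <- sum(diag(crossprod(Ynew, B %*% Ynew)))
          if (e_new <= e_cur + 1e-12) {
            Y <- Ynew
            e_cur <- e_new
          }
        }
      }
      mats[[i]] <- Y
      energy[it, i] <- e_cur
    }
  }
  out <- sample
  for (i in seq_len(n)) {
    if (inherits(out[[i]], "landmark_config")) out[[i]]$coords[] <- mats[[i]]
    else out[[i]] <- mats[[i]]
  }
  list(sample = out, energy = energy)
}

#' Estimate missing landmarks by thin-plate spline
#'
#' Fits a TPS from the reference mean's landmarks that are present in the
#' target onto the target's present landmarks; missing positions are the
#' images of the reference mean's corresponding points.  Estimated landmarks
#' are flagged and barred from subsequent sliding.
#'
#' @param incomplete a [landmark_config] with `missing` flags (or NA rows).
#' @param reference_sample a list of complete [landmark_config]s (or
#'   matrices), an `aligned_sample`, or a single k x 3 matrix; the reference
#'   mean is their arithmetic landmark-wise mean.
#' @return the completed [landmark_config]; attribute `estimated` gives the
#'   indices filled in.
#' @export
estimate_missing_tps <- function(incomplete, reference_sample) {
  stopifnot(inherits(incomplete, "landmark_config"))
  miss <- incomplete$missing
  if (!any(miss)) return(incomplete)
  ref <- if (inherits(reference_sample, "aligned_sample")) {
    apply(reference_sample$rotated, c(1L, 2L), mean)
  } else if (is.list(reference_sample)) {
    Reduce(`+`, lapply(reference_sample, lm_coords)) /
      length(reference_sample)
  } else as.matrix(reference_sample)
  if (anyNA(ref)) stop("reference sample must be complete")
  if (nrow(ref) != nrow(incomplete$coords))
    stop("reference landmark count does not match the target")
  present <- which(!miss)
  if (length(present) < 4L)
    stop("need at least 4 shared present landmarks to anchor the TPS")
  tw <- tps_fit(ref[present, , drop = FALSE],
                incomplete$coords[present, , drop = FALSE])
  est <- tps_apply(tw, ref[miss, , drop = FALSE])
  out <- incomplete
  out$coords[miss, ] <- est
  out$missing[] <- FALSE
  out$sliding[miss] <- FALSE
  attr(out, "estimated") <- which(miss)
  out
}
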