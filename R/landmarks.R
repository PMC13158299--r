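#' Landmark configuration
#'
#' The atom of the package: one specimen's k x 3 landmark coordinates (mm)
#' together with per-landmark labels, roles, a missing-data mask and sliding
#' permissions.
#'
#' @param coords numeric k x 3 matrix of coordinates in mm.  Missing landmarks
#'   are encoded as `NA` rows (or flagged through `missing`).
#' @param specimen_id character scalar identifying the specimen.
#' @param landmark_names character vector of length k; defaults to
#'   `"L1".."Lk"`.
#' @param roles character vector of length k, each one of `"anatomical"`,
#'   `"curve_semilandmark"`, `"surface_semilandmark"`.
#' @param missing logical vector of length k flagging missing landmarks.
#'   Coordinates with any `NA` are always flagged.
#' @param sliding logical vector of length k; `TRUE` where the landmark is
#'   allowed to slide.  Defaults to `roles == "curve_semilandmark"`.
#' @return an object of class `landmark_config`.
#' @examples
#' lc <- landmark_config(matrix(rnorm(12), 4, 3), "spec1")
#' centroid_size(lc)
#' @export
landmark_config <- function(coords, specimen_id = "specimen",
                            landmark_names = NULL, roles = NULL,
                            missing = NULL, sliding = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L)
    stop("'coords' must be a k x 3 matrix")
  k <- nrow(coords)
  storage.mode(coords) <- "double"
  if (is.null(landmark_names)) landmark_names <- paste0("L", seq_len(k))
  if (length(landmark_names) != k) stop("length(landmark_names) != k")
  if (is.null(roles)) roles <- rep("anatomical", k)
  roles <- match.arg(roles,
                     c("anatomical", "curve_semilandmark",
                       "surface_semilandmark"),
                     several.ok = TRUE)
  if (length(roles) == 1L) roles <- rep(roles, k)
  if (length(roles) != k) stop("length(roles) != k")
  na_row <- rowSums(is.na(coords)) > 0L
  if (is.null(missing)) missing <- na_row else missing <- missing | na_row
  if (length(missing) != k) stop("length(missing) != k")
  if (is.null(sliding)) sliding <- roles == "curve_semilandmark"
  if (length(sliding) != k) stop("length(sliding) != k")
  rownames(coords) <- landmark_names
  structure(list(specimen_id = as.character(specimen_id),
                 coords = coords,
                 landmark_names = as.character(landmark_names),
                 roles = roles,
                 missing = as.logical(missing),
                 sliding = as.logical(sliding)),
            class = "landmark_config")
}

#' @export
print.landmark_config <- function(x, ...) {
  cat(sprintf("Landmark configuration '%s': %d landmarks (%d missing)\n",
              x$specimen_id, nrow(x$coords), sum(x$missing)))
  tab <- table(x$roles)
  cat("  roles:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

# coerce matrices / configs to a bare coordinate matrix
lm_coords <- function(x) {
  if (inherits(x, "landmark_config")) x$coords else as.matrix(x)
}

#' Bilateral pairing table
#'
#' Records which landmarks form left/right bilateral pairs and which lie on
#' the midline (midsagittal plane).  Used by all symmetry operations.
#'
#' @param pairs two-column integer matrix; column 1 the left, column 2 the
#'   right member of each pair.
#' @param midline integer vector of unpaired (midline) landmark indices.
#' @param k total number of landmarks the table refers to (optional; checked
#'   when supplied).
#' @return an object of class `pairing_table`.
#' @export
pairing_table <- function(pairs, midline = integer(0), k = NULL) {
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  midline <- as.integer(midline)
  all_idx <- c(pairs, midline)
  if (anyDuplicated(all_idx))
    stop("an index appears more than once in the pairing table")
  if (!is.null(k) && !setequal(all_idx, seq_len(k)))
    stop("pairs and midline must cover all ", k, " landmarks exactly once")
  structure(list(pairs = pairs, midline = midline),
            class = "pairing_table")
}

#' @export
print.pairing_table <- function(x, ...) {
  cat(sprintf("Pairing table: %d bilateral pairs, %d midline landmarks\n",
              nrow(x$pairs), length(x$midline)))
  invisible(x)
}

# permutation that swaps left and right labels
relabel_permutation <- function(pairing, k) {
  perm <- seq_len(k)
  perm[pairing$pairs[, 1L]] <- pairing$pairs[, 2L]
  perm[pairing$pairs[, 2L]] <- pairing$pairs[, 1L]
  perm
}

#' Centroid size
#'
#' Square root of the summed squared distances of all landmarks from their
#' centroid — the standard size measure in geometric morphometrics, computed
#' on the raw (pre-alignment) coordinates.
#'
#' @param config a [landmark_config] or bare k x 3 matrix.
#' @return positive numeric scalar (mm).
#' @export
centroid_size <- function(config) {
  if (inherits(config, "landmark_config") && any(config$missing))
    stop("centroid size is undefined with missing landmarks; ",
         "estimate them first (see estimate_missing_tps)")
  x <- lm_coords(config)
  if (anyNA(x)) stop("coordinates contain NA")
  ctr <- colMeans(x)
  sqrt(sum(sweep(x, 2L, ctr)^2))
}

# center a k x 3 matrix at the origin
center_config <- function(x) sweep(x, 2L, colMeans(x))

# centered, unit-centroid-size preshape
preshape <- function(x) {
  x <- center_config(lm_coords(x))
  cs <- sqrt(sum(x^2))
  if (cs <= 0) stop("degenerate configuration (zero centroid size)")
  x / cs
}
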