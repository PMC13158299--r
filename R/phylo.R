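#' Phylogenetic covariance expanded to specimens
#'
#' Brownian-motion covariance from a rooted, branch-length-bearing tree
#' (shared root-to-MRCA path lengths, via `ape::vcv.phylo`), expanded to the
#' specimen level: conspecific specimens share their species' covariance
#' entries; a small diagonal jitter keeps the expanded matrix invertible.
#'
#' @param tree an `ape::phylo` tree, or a file path / Newick string (parsed
#'   with [read_newick()]).
#' @param species character vector mapping each specimen to a tip label.
#' @param jitter relative diagonal jitter (default 1e-8 of the mean
#'   diagonal).
#' @return object of class `phylo_covariance` with `tree`, `species`,
#'   `species_cov` and `cov` (n x n expanded matrix).
#' @export
phylo_covariance <- function(tree, species, jitter = 1e-8) {
  if (is.character(tree)) tree <- read_newick(tree)
  if (!inherits(tree, "phylo")) stop("'tree' must be an ape phylo object")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  V <- ape::vcv.phylo(tree)
  if (max(diag(V)) <= 0) stop("zero-depth tree")
  species <- as.character(species)
  missing_sp <- setdiff(unique(species), rownames(V))
  if (length(missing_sp) > 0L)
    stop("species not in the tree: ", paste(missing_sp, collapse = ", "))
  C <- V[species, species, drop = FALSE]
  C <- C + diag(jitter * mean(diag(C)), nrow(C))
  rownames(C) <- colnames(C) <- names(species) %||% species
  structure(list(tree = tree, species = species, species_cov = V, cov = C),
            class = "phylo_covariance")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Random ultrametric species tree
#'
#' Coalescent-style random rooted ultrametric tree over the given labels
#' (via `ape::rcoal`), returned as a Newick string.
#'
#' @param species_labels character vector of >= 2 tip labels.
#' @param seed optional integer seed.
#' @return Newick text (single string, terminated by `;`).
#' @export
random_species_tree <- function(species_labels, seed = NULL) {
  if (length(species_labels) < 2L) stop("need at least 2 species")
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rcoal(length(species_labels), tip.label = species_labels)
  ape::write.tree(tr)
}
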