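#' Phylogenetic correlation matrix from a tree
#'
#' Converts a phylogeny into the among-species correlation matrix \code{A}
#' used by the phylogenetic random effect. Under a Brownian-motion
#' expectation the covariance between two species is the shared
#' root-to-tip path length; scaling that covariance to a correlation
#' (unit diagonal) gives \code{A}. For an ultrametric tree this equals
#' shared depth divided by total depth.
#'
#' @param tree a Newick string, a path to a Newick file, or an
#'   \code{ape::phylo} object. Branch lengths are required.
#' @param normalize if \code{TRUE} (default) the Brownian covariance is
#'   scaled to a correlation, forcing a unit diagonal even for
#'   non-ultrametric trees.
#' @return an object of class \code{"phylo_corr"}: a list with
#'   \code{species} (tip labels, in matrix order) and \code{A} (the
#'   correlation matrix).
#' @export
newick_to_phylo_corr <- function(tree, normalize = TRUE) {
  if (inherits(tree, "phylo")) {
    phy <- tree
  } else if (is.character(tree) && length(tree) == 1L) {
    phy <- if (file.exists(tree) && !grepl("\\(", tree))
      ape::read.tree(file = tree)
    else
      tryCatch(suppressWarnings(ape::read.tree(text = tree)),
               error = function(e) NULL)
    if (is.null(phy)) .stopf("could not parse Newick tree")
  } else {
    .stopf("'tree' must be a Newick string, file path or phylo object")
  }
  if (is.null(phy$edge.length))
    .stopf("tree has no branch lengths; a correlation structure needs them")
  if (anyDuplicated(phy$tip.label))
    .stopf("tree tip labels must be unique")

  Vc <- ape::vcv(phy)
  A <- if (normalize) stats::cov2cor(Vc) else Vc
  # star trees give exact zeros; numerical noise can make vcv slightly asym.
  A <- (A + t(A)) / 2
  if (normalize) diag(A) <- 1

  lam <- .min_eigen(A)
  if (lam < -1e-10)
    .stopf("tree correlation matrix is not positive semi-definite (min eigenvalue %.3g)", lam)
  structure(list(species = rownames(A), A = A), class = "phylo_corr")
}

#' @export
print.phylo_corr <- function(x, ...) {
  cat(sprintf("Phylogenetic correlation over %d species\n", length(x$species)))
  invisible(x)
}

# check that all species labels in an effect table are covered by A
.check_phylo_coverage <- function(table, pc) {
  if (is.null(table$species))
    .stopf("data has no species column; a phylogenetic model needs one")
  miss <- setdiff(unique(table$species), pc$species)
  if (length(miss))
    .stopf("species missing from the tree: %s", paste(miss, collapse = ", "))
  invisible(TRUE)
}
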