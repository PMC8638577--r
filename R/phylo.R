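#' Read a time-calibrated phylogeny from a Newick file or string
#'
#' Wraps \code{ape::read.tree} with the validation this package's analyses
#' require: unique tip labels, branch lengths present and non-negative, and
#' (by default) a fully resolved (binary) rooted topology. Tip labels are
#' normalized by replacing underscores with spaces and collapsing
#' whitespace, so that table species names and tree tips match exactly or
#' not at all (no fuzzy matching).
#'
#' @param source Path to a \code{.nwk} file, or a Newick string.
#' @param strict If \code{TRUE} (default), polytomies are an error; if
#'   \code{FALSE} they are resolved to a binary tree with zero-length
#'   branches (\code{ape::multi2di}).
#' @param require_ultrametric If \code{TRUE}, non-ultrametric trees are an
#'   error; default \code{FALSE} emits a warning only.
#' @return An \code{ape} \code{"phylo"} tree.
#' @export
read_limb_tree <- function(source, strict = TRUE, require_ultrametric = FALSE) {
  tree <- if (length(source) == 1L && grepl("[(;]", source))
    ape::read.tree(text = source) else ape::read.tree(source)
  if (is.null(tree)) stop("could not parse Newick input")
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths; a time-calibrated tree is required")
  if (any(tree$edge.length < 0)) stop("negative branch lengths in tree")
  tree$tip.label <- normalize_taxon(tree$tip.label)
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  if (!ape::is.binary(tree)) {
    if (strict) {
      deg <- tabulate(tree$edge[, 1L])
      poly <- which(deg > 2L)
      stop("tree contains polytomies (internal node(s) ",
           paste(poly, collapse = ", "),
           "); resolve them or use strict = FALSE")
    }
    tree <- ape::multi2di(tree)
  }
  if (ape::Ntip(tree) >= 3L && !ape::is.ultrametric(tree, tol = 1e-6)) {
    if (require_ultrametric) stop("tree is not ultrametric")
    warning("tree is not ultrametric; lambda-scaled covariances remain defined")
  }
  tree
}

#' Normalize taxon names for exact matching
#'
#' Underscores become spaces, runs of whitespace collapse, and leading or
#' trailing whitespace is dropped. No other transformation is applied;
#' substitutions of one species for another belong in the caller's
#' configuration, never here.
#'
#' @param x Character vector of names.
#' @return Normalized names.
#' @export
normalize_taxon <- function(x) {
  x <- gsub("_", " ", x, fixed = TRUE)
  trimws(gsub("[[:space:]]+", " ", x))
}

#' Brownian-motion phylogenetic covariance matrix, with optional lambda
#'
#' Builds the among-species covariance matrix implied by Brownian motion on
#' a time-calibrated tree: entry (i, j) is the shared root-to-tip path
#' length of taxa i and j (the depth of their most recent common ancestor),
#' and the diagonal holds the root-to-tip depths. Off-diagonals are then
#' scaled by Pagel's lambda.
#'
#' @param tree A \code{"phylo"} tree with branch lengths.
#' @param taxa Optional ordered taxon names selecting/ordering rows; all
#'   must be tips of the tree (after [normalize_taxon()]).
#' @param lambda Pagel's lambda in [0, 1] (default 1, plain Brownian).
#' @return A symmetric matrix with \code{dimnames} equal to the taxa, of
#'   class \code{"phylo_vcv"} carrying a \code{"lambda"} attribute.
#' @examples
#' tr <- read_limb_tree("((A:1,B:1):1,C:2);")
#' phylo_vcv(tr)
#' phylo_vcv(tr, lambda = 0.5)
#' @export
phylo_vcv <- function(tree, taxa = NULL, lambda = 1) {
  V <- ape::vcv.phylo(tree)
  colnames(V) <- rownames(V) <- normalize_taxon(rownames(V))
  if (!is.null(taxa)) {
    taxa <- normalize_taxon(taxa)
    unknown <- setdiff(taxa, rownames(V))
    if (length(unknown))
      stop("taxa not found in tree: ", paste(unknown, collapse = ", "))
    V <- V[taxa, taxa, drop = FALSE]
  }
  lambda_transform(structure(V, class = c("phylo_vcv", "matrix"), lambda = 1),
                   lambda)
}

#' Scale the off-diagonals of a phylogenetic covariance matrix by lambda
#'
#' Pagel's lambda transform: off-diagonal entries are multiplied by
#' \code{lambda}, diagonals are untouched. \code{lambda = 1} is the
#' identity; \code{lambda = 0} removes all phylogenetic covariance. On an
#' ultrametric-tree covariance the result is positive-definite for every
#' lambda in [0, 1].
#'
#' @param V A covariance matrix (typically from [phylo_vcv()] at lambda 1).
#' @param lambda A number in [0, 1].
#' @return The transformed matrix, with its \code{"lambda"} attribute
#'   multiplied accordingly.
#' @export
lambda_transform <- function(V, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1L || !is.finite(lambda) ||
      lambda < 0 || lambda > 1)
    stop("'lambda' must be a single number in [0, 1]")
  d <- diag(V)
  out <- V * lambda
  diag(out) <- d
  prev <- attr(V, "lambda")
  structure(out, class = c("phylo_vcv", "matrix"),
            lambda = if (is.null(prev)) lambda else prev * lambda)
}

#' Prune a tree to a set of taxa, preserving path lengths
#'
#' Returns the induced subtree on \code{taxa}: internal degree-2 nodes are
#' collapsed and their branch lengths summed, so that the covariance matrix
#' of the pruned tree equals the corresponding submatrix of the full tree's
#' covariance matrix.
#'
#' @param tree A \code{"phylo"} tree.
#' @param taxa Non-empty set of tip names to keep.
#' @return The pruned \code{"phylo"} tree.
#' @export
prune_taxa <- function(tree, taxa) {
  taxa <- normalize_taxon(taxa)
  if (length(taxa) == 0L) stop("'taxa' must be non-empty")
  tree$tip.label <- normalize_taxon(tree$tip.label)
  unknown <- setdiff(taxa, tree$tip.label)
  if (length(unknown))
    stop("taxa not found in tree: ", paste(unknown, collapse = ", "))
  ape::keep.tip(tree, taxa)
}

#' Write a tree to a Newick file
#'
#' @param tree A \code{"phylo"} tree.
#' @param path Output path (\code{.nwk}). Branch lengths are written with
#'   enough digits to round-trip to within 1e-9.
#' @return \code{path}, invisibly.
#' @export
write_limb_tree <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}
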