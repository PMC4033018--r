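#' Load a dated phylogeny from Newick
#'
#' Reads a rooted Newick tree with branch lengths (millions of years),
#' resolves polytomies deterministically into bifurcations with zero-length
#' inserted branches, and attaches an ultrametricity report. Duplicate tip
#' labels and unrooted or unparseable trees are errors.
#'
#' @param path path to a Newick file, or a Newick string (detected by a
#'   trailing ";").
#' @param tol relative ultrametricity tolerance: the spread of root-to-tip
#'   depths must be at most `tol` times the tree depth for the tree to be
#'   flagged ultrametric.
#' @return an `ape` `phylo` object with attributes `ultrametric` (logical),
#'   `depth` (max root-to-tip path length) and `depth_spread`.
#' @export
#' @examples
#' tr <- read_phylo("((A:1,B:1):1,C:2);")
#' attr(tr, "ultrametric")
read_phylo <- function(path, tol = 1e-6) {
  is_text <- grepl(";[[:space:]]*$", path[1]) && !file.exists(path[1])
  phy <- if (is_text) ape::read.tree(text = path) else {
    if (!file.exists(path)) stop("tree file not found: ", path, call. = FALSE)
    ape::read.tree(path)
  }
  if (is.null(phy)) stop("could not parse Newick input", call. = FALSE)
  if (is.null(phy$edge.length)) {
    stop("tree has no branch lengths", call. = FALSE)
  }
  if (anyDuplicated(phy$tip.label)) {
    stop("duplicate tip labels: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]),
               collapse = ", "), call. = FALSE)
  }
  if (!ape::is.binary(phy) || !ape::is.rooted(phy)) {
    # covers basal polytomies too, which Newick cannot distinguish from
    # unrooted trees; resolution roots them deterministically
    phy <- ape::multi2di(phy, random = FALSE)  # zero-length inserted branches
  }
  if (!ape::is.rooted(phy)) stop("tree must be rooted", call. = FALSE)
  if (any(phy$edge.length < 0)) {
    stop("negative branch lengths", call. = FALSE)
  }
  depths <- ape::node.depth.edgelength(phy)[seq_len(ape::Ntip(phy))]
  depth <- max(depths)
  spread <- diff(range(depths))
  attr(phy, "ultrametric") <- spread <= tol * depth
  attr(phy, "depth") <- depth
  attr(phy, "depth_spread") <- spread
  phy
}

# Re-attach the ultrametricity report after pruning/ladderizing.
annotate_depth <- function(phy, tol = 1e-6) {
  depths <- ape::node.depth.edgelength(phy)[seq_len(ape::Ntip(phy))]
  attr(phy, "ultrametric") <- diff(range(depths)) <= tol * max(depths)
  attr(phy, "depth") <- max(depths)
  phy
}

# Prune a tree to a species set, matching names after whitespace/underscore
# normalization. `labels` are the caller's names; tip labels are rewritten
# to the caller's spelling so downstream matching is exact.
prune_to_species <- function(phy, labels) {
  tips_norm <- normalize_taxon(phy$tip.label)
  want_norm <- normalize_taxon(labels)
  miss <- labels[!want_norm %in% tips_norm]
  if (length(miss)) {
    stop("species not in tree: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  keep <- phy$tip.label[match(want_norm, tips_norm)]
  out <- ape::keep.tip(phy, keep)
  out$tip.label <- labels[match(normalize_taxon(out$tip.label), want_norm)]
  annotate_depth(out)
}

#' Brownian-motion phylogenetic covariance matrix
#'
#' Entry (i, j) is the shared root-to-tip path length of tips i and j (the
#' depth of their most recent common ancestor); the diagonal holds each
#' tip's own root-to-tip depth. Under Brownian motion the trait covariance
#' is proportional to this matrix.
#'
#' @param phy a `phylo` tree with branch lengths.
#' @param tips optional subset (and ordering) of taxon names; the tree is
#'   pruned to these before computing. Names are matched after
#'   underscore/space normalization.
#' @return a symmetric matrix with `tips` (or the tree's tip labels) as
#'   dimnames.
#' @export
#' @examples
#' bm_covariance(read_phylo("((A:1,B:1):1,C:2);"))
bm_covariance <- function(phy, tips = NULL) {
  if (!is.null(tips)) phy <- prune_to_species(phy, tips)
  V <- ape::vcv(phy)
  if (!is.null(tips)) V <- V[tips, tips, drop = FALSE]
  V
}

#' Pagel's lambda transform of a phylogenetic covariance matrix
#'
#' Multiplies the off-diagonal entries (shared history) by `lambda` while
#' leaving the diagonal untouched. `lambda = 1` returns the Brownian
#' covariance unchanged; `lambda = 0` removes all phylogenetic covariance.
#'
#' @param V covariance matrix from [bm_covariance()].
#' @param lambda signal strength in `[0, 1]`.
#' @return the transformed matrix.
#' @export
lambda_transform <- function(V, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) ||
      lambda < 0 || lambda > 1) {
    stop("lambda must be a single value in [0, 1]", call. = FALSE)
  }
  W <- V * lambda
  diag(W) <- diag(V)
  W
}
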