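#' Felsenstein independent contrasts by the pruning recursion
#'
#' Implements the classic pruning pass: at each internal node of a
#' bifurcating tree with child values `xi, xj` on (possibly lengthened)
#' branches `vi, vj`, the standardized contrast is `(xi - xj)/sqrt(vi + vj)`,
#' the node's estimated ancestral value is the branch-length-weighted
#' average `(xi/vi + xj/vj)/(1/vi + 1/vj)`, and the node's own parent
#' branch is lengthened by `vi*vj/(vi + vj)`. Zero-length branches (from
#' resolved polytomies) are floored at 1e-8 for standardization only.
#'
#' @param tree a bifurcating `phylo` tree (polytomies are resolved
#'   automatically as in [read_phylo()]).
#' @param trait named numeric vector of tip values, or a matrix/data.frame
#'   with one column per variable and species as rownames. All tips must
#'   be valued.
#' @return a `contrast_set`: list with `contrasts` (an (n-1) x p matrix,
#'   rows in pruning order), `sum_branch` (the lengthened `vi + vj` of each
#'   contrast), `node_values` (ancestral estimates per internal node),
#'   `root_values` (ancestral estimate at the root), and `n_tips`.
#' @export
#' @examples
#' tr <- read_phylo("(A:1,B:1);")
#' compute_contrasts(tr, c(A = 3, B = 1))$contrasts  # (3-1)/sqrt(2)
compute_contrasts <- function(tree, trait) {
  if (!ape::is.binary(tree)) tree <- ape::multi2di(tree, random = FALSE)
  X <- if (is.matrix(trait) || is.data.frame(trait)) {
    as.matrix(trait)
  } else {
    matrix(trait, ncol = 1, dimnames = list(names(trait), "trait"))
  }
  ntip <- ape::Ntip(tree)
  if (is.null(rownames(X))) {
    if (nrow(X) != ntip) stop("unnamed trait length != number of tips",
                              call. = FALSE)
    rownames(X) <- tree$tip.label
  }
  rn <- normalize_taxon(rownames(X))
  tips_norm <- normalize_taxon(tree$tip.label)
  miss <- setdiff(tips_norm, rn)
  if (length(miss)) {
    stop("missing trait value for tip(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  X <- X[match(tips_norm, rn), , drop = FALSE]
  if (anyNA(X)) stop("NA trait values are not allowed", call. = FALSE)

  eps <- 1e-8
  phy <- ape::reorder.phylo(tree, "postorder")
  nnode <- phy$Nnode
  p <- ncol(X)
  vals <- matrix(NA_real_, ntip + nnode, p)
  vals[seq_len(ntip), ] <- X
  # branch length above each node, lengthened as pruning proceeds
  blen <- numeric(ntip + nnode)
  blen[phy$edge[, 2]] <- phy$edge.length

  contrasts <- matrix(NA_real_, nnode, p)
  sum_branch <- numeric(nnode)
  node_ids <- integer(nnode)
  k <- 0L
  i <- 1L
  edge <- phy$edge
  while (i < nrow(edge)) {
    parent <- edge[i, 1]
    stopifnot(edge[i + 1L, 1] == parent)  # postorder pairs children
    c1 <- edge[i, 2]; c2 <- edge[i + 1L, 2]
    v1 <- max(blen[c1], eps); v2 <- max(blen[c2], eps)
    k <- k + 1L
    contrasts[k, ] <- (vals[c1, ] - vals[c2, ]) / sqrt(v1 + v2)
    sum_branch[k] <- v1 + v2
    vals[parent, ] <- (vals[c1, ] / v1 + vals[c2, ] / v2) / (1 / v1 + 1 / v2)
    blen[parent] <- blen[parent] + v1 * v2 / (v1 + v2)
    node_ids[k] <- parent
    i <- i + 2L
  }
  colnames(contrasts) <- colnames(X)
  colnames(vals) <- colnames(X)
  root <- ntip + 1L
  structure(list(contrasts = contrasts, sum_branch = sum_branch,
                 node_values = vals[(ntip + 1L):(ntip + nnode), , drop = FALSE],
                 node_ids = node_ids,
                 root_values = vals[root, ],
                 n_tips = ntip),
            class = "contrast_set")
}

#' Diagnose whether branch lengths need transforming for contrasts
#'
#' The standard adequacy check for independent contrasts: absolute
#' standardized contrasts should be uncorrelated with the square root of
#' their (lengthened) branch-length sums. A significant positive or
#' negative Pearson correlation suggests the branch lengths should be
#' transformed before contrasts are trusted.
#'
#' @param cs a `contrast_set` from [compute_contrasts()].
#' @param variable column (name or index) of the contrast matrix to check;
#'   default first.
#' @param alpha significance threshold for the recommendation flag.
#' @return list with `r` (Pearson correlation, `NA` when undefined), `p`,
#'   and `transform_recommended`.
#' @export
diagnose_branch_lengths <- function(cs, variable = 1L, alpha = 0.05) {
  stopifnot(inherits(cs, "contrast_set"))
  ac <- abs(cs$contrasts[, variable])
  if (length(ac) < 3) stop("need at least 3 contrasts", call. = FALSE)
  sb <- sqrt(cs$sum_branch)
  if (sd(ac) == 0 || sd(sb) == 0) {
    return(list(r = NA_real_, p = NA_real_, transform_recommended = FALSE))
  }
  ct <- cor.test(ac, sb, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value,
       transform_recommended = ct$p.value < alpha)
}
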