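# Brute-force phylogenetic covariance: walk every root-to-tip path and sum
# the lengths of the shared edges of each tip pair. Independent of the
# package's covariance code.
brute_force_vcv <- function(phy) {
  ntip <- ape::Ntip(phy)
  root <- ntip + 1L
  # edge path (edge indices) from root to each tip
  parent_edge <- integer(ntip + phy$Nnode)
  parent_edge[phy$edge[, 2]] <- seq_len(nrow(phy$edge))
  path_to <- function(node) {
    edges <- integer(0)
    while (node != root) {
      e <- parent_edge[node]
      edges <- c(edges, e)
      node <- phy$edge[e, 1]
    }
    edges
  }
  paths <- lapply(seq_len(ntip), path_to)
  V <- matrix(0, ntip, ntip,
              dimnames = list(phy$tip.label, phy$tip.label))
  for (i in seq_len(ntip)) {
    for (j in seq_len(ntip)) {
      shared <- intersect(paths[[i]], paths[[j]])
      V[i, j] <- sum(phy$edge.length[shared])
    }
  }
  V
}

# Draw one trait vector with covariance sigma2 * V (test-side sampler).
rmvn_chol <- function(V, sigma = 1) {
  drop(crossprod(chol(V), stats::rnorm(nrow(V)))) * sigma
}

# Published summary-table inputs used by the classification-consistency
# checks: two-sided 95% PI bounds (log10 cc) per subcortical structure in
# the hominoid analysis, and the structure's observed human volume (cc).
hominoid_printed_pi <- data.frame(
  structure = c("amygdala", "lateral_nucleus", "basal_nucleus",
                "accessory_basal_nucleus", "central_nucleus",
                "hippocampus", "striatum"),
  lower = c(0.23, -0.56, -0.33, -0.84, -0.98, 0.27, 0.91),
  upper = c(0.33, -0.35, -0.13, -0.38, -0.61, 0.56, 1.25),
  human = c(2.031, 0.551, 0.452, 0.188, 0.039, 5.180, 10.887),
  expected = c("within", "significantly_above", "significantly_below",
               "within", "significantly_below", "significantly_above",
               "within"),
  stringsAsFactors = FALSE)
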