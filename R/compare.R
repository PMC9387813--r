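#' Non-trivial bipartitions of a tree
#'
#' Every internal edge of an unrooted tree splits the tips into two blocks;
#' the split is canonicalized as the sorted label set of the block NOT
#' containing the alphabetically first tip, and trivial splits (a block of
#' fewer than two tips) are dropped. These keys underlie the
#' Robinson-Foulds-style concordance and the bootstrap counting.
#'
#' @param tree An `ape::phylo`.
#' @return A character vector of canonical split keys (labels joined by
#'   `"|"`), possibly empty.
#' @export
tree_bipartitions <- function(tree) {
  unique(unname(node_bipartition_keys(tree)))
}

# Canonical split key per internal node (named by node id when named = TRUE).
# Nodes whose split is trivial are omitted.
node_bipartition_keys <- function(tree, named = FALSE) {
  tips <- tree$tip.label
  n <- length(tips)
  ref <- sort(tips)[1]
  pp <- ape::prop.part(tree)
  out <- character(0)
  ids <- integer(0)
  for (k in seq_along(pp)) {
    block <- tips[pp[[k]]]
    if (ref %in% block) block <- setdiff(tips, block)
    if (length(block) < 2 || length(block) > n - 2) next
    out <- c(out, paste(sort(block), collapse = "|"))
    ids <- c(ids, n + k) # prop.part entries follow internal node numbering
  }
  if (named) names(out) <- ids
  out
}

#' Patristic (tip-to-tip path length) distance matrix
#'
#' @param tree An `ape::phylo` with branch lengths.
#' @return A symmetric matrix of path-length sums between tips.
#' @export
patristic_matrix <- function(tree) {
  if (is.null(tree$edge.length)) abort("tree has no branch lengths")
  stats::cophenetic(tree)
}

#' Prune two trees to their common tips
#'
#' Tips absent from either tree are dropped; resulting degree-2 nodes are
#' suppressed with their incident branch lengths summed, so patristic
#' distances among the surviving tips are preserved.
#'
#' @param tree_a,tree_b `ape::phylo` trees.
#' @return A list with elements `tree_a` and `tree_b`.
#' @export
prune_to_common <- function(tree_a, tree_b) {
  common <- intersect(tree_a$tip.label, tree_b$tip.label)
  if (!length(common)) abort("trees share no tips")
  prune1 <- function(tr) {
    if (length(common) == length(tr$tip.label)) tr else ape::keep.tip(tr, common)
  }
  list(tree_a = prune1(tree_a), tree_b = prune1(tree_b))
}

#' Correlation of patristic distances between two trees
#'
#' Both trees are pruned to their common tips; Pearson and Spearman
#' correlations are computed over the upper triangle of the two aligned
#' patristic matrices. A zero-variance matrix yields `NA` correlations
#' with a warning.
#'
#' @param tree_a,tree_b `ape::phylo` trees with branch lengths, sharing at
#'   least 4 tips.
#' @return A one-row tibble: `n_common_tips`, `pearson_r`, `spearman_rho`.
#' @export
tree_distance_correlation <- function(tree_a, tree_b) {
  pr <- prune_to_common(tree_a, tree_b)
  tips <- sort(pr$tree_a$tip.label)
  if (length(tips) < 4) abort("need at least 4 common tips")
  da <- patristic_matrix(pr$tree_a)[tips, tips]
  db <- patristic_matrix(pr$tree_b)[tips, tips]
  va <- da[upper.tri(da)]
  vb <- db[upper.tri(db)]
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    warn("zero variance in patristic distances; correlation undefined")
    return(tibble(
      n_common_tips = length(tips),
      pearson_r = NA_real_, spearman_rho = NA_real_
    ))
  }
  tibble(
    n_common_tips = length(tips),
    pearson_r = cor(va, vb, method = "pearson"),
    spearman_rho = cor(va, vb, method = "spearman")
  )
}

#' Clade concordance between a reference and a comparison tree
#'
#' Both trees are pruned to their common tips (at least 4); the
#' concordance is the fraction of the pruned reference tree's non-trivial
#' bipartitions that also occur in the pruned comparison tree — i.e.
#' 1 minus the one-sided normalized Robinson-Foulds distance. Identical
#' trees score 1; a fully resolved reference against a star scores 0. If
#' the pruned reference has no non-trivial bipartition the value is
#' undefined (`NA` with a warning).
#'
#' @param reference_tree,comparison_tree `ape::phylo` trees.
#' @return A number in `[0, 1]`, or `NA`.
#' @export
clade_concordance <- function(reference_tree, comparison_tree) {
  pr <- prune_to_common(reference_tree, comparison_tree)
  if (length(pr$tree_a$tip.label) < 4) abort("need at least 4 common tips")
  ref_splits <- tree_bipartitions(pr$tree_a)
  if (!length(ref_splits)) {
    warn("pruned reference tree is fully unresolved; concordance undefined")
    return(NA_real_)
  }
  cmp_splits <- tree_bipartitions(pr$tree_b)
  length(intersect(ref_splits, cmp_splits)) / length(ref_splits)
}
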