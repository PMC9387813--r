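# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths (and ape's where the package uses ape).

# H by explicit tallying with table()
oracle_H <- function(chars) {
  tab <- table(factor(chars, levels = c("A", "C", "G", "T", "-")))
  1 - sum(as.numeric(tab)^2) / length(chars)^2
}

# tips below a node by naive recursion over the edge matrix
oracle_tips_below <- function(tree, node) {
  nt <- length(tree$tip.label)
  if (node <= nt) {
    return(tree$tip.label[node])
  }
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, function(k) oracle_tips_below(tree, k)))
}

# canonical non-trivial split keys by enumerating internal edges
oracle_bipartitions <- function(tree) {
  nt <- length(tree$tip.label)
  ref <- sort(tree$tip.label)[1]
  inner <- tree$edge[, 2][tree$edge[, 2] > nt]
  keys <- character(0)
  for (nd in inner) {
    block <- oracle_tips_below(tree, nd)
    if (ref %in% block) block <- setdiff(tree$tip.label, block)
    if (length(block) >= 2 && length(block) <= nt - 2) {
      keys <- c(keys, paste(sort(block), collapse = "|"))
    }
  }
  unique(keys)
}

# patristic distances via node depths and explicit ancestor sets
oracle_patristic <- function(tree) {
  nt <- length(tree$tip.label)
  nn <- max(tree$edge)
  parent <- integer(nn)
  elen <- numeric(nn)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen[tree$edge[, 2]] <- tree$edge.length
  depth <- function(v) {
    d <- 0
    while (parent[v] != 0) {
      d <- d + elen[v]
      v <- parent[v]
    }
    d
  }
  ancestors <- function(v) {
    out <- v
    while (parent[v] != 0) {
      v <- parent[v]
      out <- c(out, v)
    }
    out
  }
  D <- matrix(0, nt, nt, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(nt - 1)) {
    ai <- ancestors(i)
    for (j in (i + 1):nt) {
      mrca <- intersect(ai, ancestors(j))[1]
      D[i, j] <- D[j, i] <- depth(i) + depth(j) - 2 * depth(mrca)
    }
  }
  D
}

# pairwise-deletion p-distance by a plain per-site loop over one pair
oracle_p_distance <- function(si, sj) {
  ok <- si != "-" & sj != "-"
  if (!any(ok)) {
    return(NA_real_)
  }
  sum(si[ok] != sj[ok]) / sum(ok)
}

# Mann-Whitney U by pair counting (greater: x over y)
oracle_mwu <- function(x, y) {
  sum(outer(x, y, function(a, b) (a > b) + 0.5 * (a == b)))
}

# random gapped alignment matrix
random_alignment <- function(n_taxa, n_cols, gap_prob = 0.05) {
  m <- matrix(
    sample(c("A", "C", "G", "T"), n_taxa * n_cols, replace = TRUE),
    nrow = n_taxa
  )
  gaps <- matrix(runif(n_taxa * n_cols) < gap_prob, nrow = n_taxa)
  m[gaps] <- "-"
  rownames(m) <- sprintf("s%02d", seq_len(n_taxa))
  m
}

# random binary tree with positive branch lengths (input generator)
random_bl_tree <- function(n) {
  tr <- ape::rtree(n, rooted = FALSE)
  tr$edge.length <- runif(length(tr$edge.length), 0.05, 1)
  tr
}
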