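#' Pairwise evolutionary distances from an alignment
#'
#' Distances use pairwise deletion: for each pair of sequences only the
#' sites where neither member has a gap are compared. `model = "p"` gives
#' the raw mismatch proportion; `model = "jc69"` applies the Jukes-Cantor
#' correction \eqn{d = -\frac{3}{4}\ln(1 - \frac{4}{3}p)}. The computation
#' is fully vectorized via indicator-matrix products, so full mitogenome
#' alignments with a hundred taxa are handled in well under a second.
#'
#' @param aln An [annotated_alignment()] with at least two taxa.
#' @param model `"p"` or `"jc69"`.
#' @param cap_saturation With `jc69`, cap saturated pairs (`p >= 0.75`) at
#'   the distance of `p = 0.7499` (with a warning) instead of erroring.
#' @return A symmetric numeric matrix with taxon dimnames and zero
#'   diagonal.
#' @export
pairwise_distance <- function(aln, model = c("p", "jc69"), cap_saturation = FALSE) {
  model <- match.arg(model)
  m <- aln_matrix(aln)
  if (nrow(m) < 2) abort("need at least two taxa")
  ng <- (m != "-") * 1
  valid <- ng %*% t(ng)
  match_ct <- matrix(0, nrow(m), nrow(m))
  for (b in c("A", "C", "G", "T")) {
    x <- (m == b) * 1
    match_ct <- match_ct + x %*% t(x)
  }
  off <- upper.tri(valid)
  if (any(valid[off] == 0)) {
    idx <- which(valid == 0 & off, arr.ind = TRUE)[1, ]
    abort(sprintf(
      "no comparable (gap-free in both) sites between %s and %s",
      rownames(m)[idx[1]], rownames(m)[idx[2]]
    ))
  }
  p <- (valid - match_ct) / valid
  diag(p) <- 0
  d <- p
  if (model == "jc69") {
    sat <- p >= 0.75 & row(p) != col(p)
    if (any(sat)) {
      if (!cap_saturation) {
        idx <- which(sat & off, arr.ind = TRUE)[1, ]
        abort(sprintf(
          "jc69 saturation (p >= 0.75) between %s and %s; use cap_saturation = TRUE",
          rownames(m)[idx[1]], rownames(m)[idx[2]]
        ))
      }
      warn(sprintf("%d saturated pair(s) capped at p = 0.7499", sum(sat & off)))
      p[sat] <- 0.7499
    }
    d <- -0.75 * log(1 - 4 * p / 3)
    diag(d) <- 0
  }
  dimnames(d) <- list(rownames(m), rownames(m))
  d
}

check_distance_matrix <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) abort("distance input must be a square matrix")
  if (is.null(rownames(d))) abort("distance matrix needs taxon labels as dimnames")
  if (any(d < 0)) abort("negative distances")
  if (max(abs(d - t(d))) > 1e-8) abort("distance matrix is not symmetric")
  invisible(d)
}

quote_label <- function(x) {
  ifelse(grepl("[ ():,;\\[\\]']", x), paste0("'", gsub("'", "''", x), "'"), x)
}

#' Neighbor-joining tree from a distance matrix
#'
#' The Saitou-Nei agglomeration: repeatedly join the pair minimizing the
#' Q-criterion, with deterministic tie-breaking (the smallest pair in the
#' current label order). Estimated negative branch lengths are clamped to
#' zero with a warning. On an exactly additive matrix the algorithm
#' recovers the generating topology and branch lengths.
#'
#' @param d A symmetric distance matrix with taxon dimnames (>= 3 taxa).
#' @return An unrooted `ape::phylo` tree.
#' @export
neighbor_joining <- function(d) {
  check_distance_matrix(d)
  n <- nrow(d)
  if (n < 3) abort("neighbor joining needs at least 3 taxa")
  labs <- quote_label(rownames(d))
  sub <- labs # growing newick fragments per active node
  D <- unname(d)
  clamped <- FALSE
  br <- function(x) {
    if (x < 0) {
      clamped <<- TRUE
      x <- 0
    }
    sprintf("%.15g", x)
  }
  while (length(sub) > 3) {
    nn <- length(sub)
    r <- rowSums(D)
    Q <- (nn - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    hits <- which(Q == min(Q), arr.ind = TRUE)
    hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
    hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
    i <- hits[1, 1]
    j <- hits[1, 2]
    bi <- 0.5 * D[i, j] + (r[i] - r[j]) / (2 * (nn - 2))
    bj <- D[i, j] - bi
    merged <- sprintf("(%s:%s,%s:%s)", sub[i], br(bi), sub[j], br(bj))
    dnew <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    keep <- setdiff(seq_len(nn), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]), c(dnew[keep], 0))
    sub <- c(sub[keep], merged)
  }
  b1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  b2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  b3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  nwk <- sprintf(
    "(%s:%s,%s:%s,%s:%s);",
    sub[1], br(b1), sub[2], br(b2), sub[3], br(b3)
  )
  if (clamped) warn("negative branch length estimate(s) clamped to 0")
  ape::read.tree(text = nwk)
}

#' Root a tree on an outgroup tip
#'
#' Places the root at the midpoint of the outgroup's pendant edge; ingroup
#' bipartitions are unchanged.
#'
#' @param tree An `ape::phylo`.
#' @param outgroup_label A tip label.
#' @return A rooted `ape::phylo`.
#' @export
root_with_outgroup <- function(tree, outgroup_label) {
  if (!outgroup_label %in% tree$tip.label) {
    abort(paste0("outgroup tip not in tree: ", outgroup_label))
  }
  rt <- ape::root(tree, outgroup = outgroup_label, resolve.root = TRUE)
  # split the outgroup pendant edge evenly across the two root edges
  root_node <- length(rt$tip.label) + 1L
  kids <- which(rt$edge[, 1] == root_node)
  if (length(kids) == 2) {
    total <- sum(rt$edge.length[kids])
    rt$edge.length[kids] <- total / 2
  }
  rt
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Builds the point-estimate NJ tree from the full alignment, then
#' `n_reps` trees from column resamples (with replacement, original
#' length). The support of each internal edge is the fraction of usable
#' replicates whose tree contains the same bipartition. Replicates whose
#' resampled columns leave some pair with no comparable sites (or
#' saturated under `jc69`) are dropped and counted; more than 20% dropped
#' is an error.
#'
#' @inheritParams pairwise_distance
#' @param n_reps Number of bootstrap replicates (>= 1).
#' @param seed Integer seed; same seed, same supports.
#' @param keep_replicates Also return each usable replicate's bipartition
#'   set (attribute `replicate_splits`), e.g. for auditing the counts.
#' @return The point-estimate tree with `node.label` holding supports in
#'   `[0, 1]` (`NA` for the root) and attribute `n_dropped`.
#' @export
bootstrap_support <- function(aln, model = c("p", "jc69"), n_reps = 100L, seed = 1L,
                              cap_saturation = FALSE, keep_replicates = FALSE) {
  model <- match.arg(model)
  if (n_reps < 1) abort("n_reps must be >= 1")
  m <- aln_matrix(aln)
  point <- neighbor_joining(pairwise_distance(aln, model, cap_saturation))
  keys <- node_bipartition_keys(point)
  counts <- setNames(numeric(length(keys)), keys)
  set.seed(as.integer(seed))
  used <- 0L
  dropped <- 0L
  rep_splits <- list()
  for (r in seq_len(n_reps)) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    rep_aln <- annotated_alignment(m[, cols, drop = FALSE], circular = FALSE)
    tr <- tryCatch(
      suppressWarnings(neighbor_joining(pairwise_distance(rep_aln, model, cap_saturation))),
      error = function(e) NULL
    )
    if (is.null(tr)) {
      dropped <- dropped + 1L
      next
    }
    used <- used + 1L
    splits <- tree_bipartitions(tr)
    if (keep_replicates) rep_splits[[used]] <- splits
    hit <- keys %in% splits
    counts[hit] <- counts[hit] + 1
  }
  if (dropped > 0.2 * n_reps) {
    abort(sprintf("%d of %d bootstrap replicates unusable (> 20%%)", dropped, n_reps))
  }
  support <- counts / max(used, 1L)
  # node labels: one per internal node; root and nodes giving trivial
  # splits carry NA
  nt <- length(point$tip.label)
  labs <- rep(NA_real_, point$Nnode)
  node_keys <- node_bipartition_keys(point, named = TRUE)
  for (nd in names(node_keys)) {
    labs[as.integer(nd) - nt] <- support[[node_keys[[nd]]]]
  }
  point$node.label <- labs
  attr(point, "n_dropped") <- dropped
  if (keep_replicates) attr(point, "replicate_splits") <- rep_splits
  point
}
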