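test_that("pairwise distances match a per-site counting oracle", {
  set.seed(21)
  m <- random_alignment(4, 200, gap_prob = 0.1)
  aln <- annotated_alignment(m, circular = FALSE)
  d <- pairwise_distance(aln, "p")
  for (i in 1:3) {
    for (j in (i + 1):4) {
      expect_equal(d[i, j], oracle_p_distance(m[i, ], m[j, ]))
    }
  }
  expect_true(isSymmetric(d))
  expect_true(all(diag(d) == 0))

  # identical sequences: zero under both models; jc69 continuous at p = 0
  two <- annotated_alignment(rbind(x = m[1, ], y = m[1, ]), circular = FALSE)
  expect_equal(unname(pairwise_distance(two, "p")[1, 2]), 0)
  expect_equal(unname(pairwise_distance(two, "jc69")[1, 2]), 0)

  # jc69 is the standard transform of p and increases with p on [0, 0.75)
  base <- sample(c("A", "C", "G", "T"), 400, replace = TRUE)
  div <- rbind(x = base, y = base, z = base)
  for (r in 2:3) {
    hit <- runif(400) < 0.2
    div[r, hit] <- sample(c("A", "C", "G", "T"), sum(hit), replace = TRUE)
  }
  dd <- pairwise_distance(annotated_alignment(div, circular = FALSE), "p")
  dj <- pairwise_distance(annotated_alignment(div, circular = FALSE), "jc69")
  expect_equal(dj[upper.tri(dj)], -0.75 * log(1 - 4 * dd[upper.tri(dd)] / 3))
  p <- seq(0, 0.74, by = 0.01)
  expect_true(all(diff(-0.75 * log(1 - 4 * p / 3)) > 0))
})

test_that("degenerate pairs raise the specified errors", {
  disjoint <- annotated_alignment(
    rbind(x = c("A", "A", "-", "-"), y = c("-", "-", "A", "A")),
    circular = FALSE
  )
  expect_error(pairwise_distance(disjoint, "p"), "no comparable")

  sat <- annotated_alignment(
    rbind(x = rep(c("A", "C"), 10), y = rep(c("C", "A"), 10)),
    circular = FALSE
  )
  expect_error(pairwise_distance(sat, "jc69"), "saturation")
  expect_warning(dc <- pairwise_distance(sat, "jc69", cap_saturation = TRUE), "capped")
  expect_true(is.finite(dc[1, 2]))
})

test_that("neighbor joining solves the 3-taxon case in closed form", {
  d <- matrix(c(0, 0.3, 0.5, 0.3, 0, 0.6, 0.5, 0.6, 0), 3,
    dimnames = list(c("a", "b", "c"), c("a", "b", "c"))
  )
  tr <- neighbor_joining(d)
  pm <- patristic_matrix(tr)[c("a", "b", "c"), c("a", "b", "c")]
  expect_equal(pm, d, tolerance = 1e-12)
  # pendant branches: (dab + dac - dbc)/2 etc.
  ba <- tr$edge.length[tr$edge[, 2] == which(tr$tip.label == "a")]
  expect_equal(ba, (0.3 + 0.5 - 0.6) / 2)

  expect_error(neighbor_joining(d * -1), "negative")
  expect_error(neighbor_joining(d[1:2, 1:2]), "at least 3")

  neg <- matrix(c(0, 0.1, 0.1, 0.1, 0, 0.3, 0.1, 0.3, 0), 3,
    dimnames = list(letters[1:3], letters[1:3])
  )
  expect_warning(neighbor_joining(neg), "clamped")
})

test_that("NJ is consistent on additive matrices from random trees", {
  set.seed(22)
  for (rep in 1:25) {
    n <- sample(5:8, 1)
    true <- random_bl_tree(n)
    d <- oracle_patristic(true)
    nj <- neighbor_joining(d)
    expect_setequal(tree_bipartitions(nj), oracle_bipartitions(true))
    pm <- patristic_matrix(nj)[rownames(d), colnames(d)]
    expect_lt(max(abs(pm - d)), 1e-9)
  }
})

test_that("NJ agrees with the least-squares best quartet and with ape", {
  set.seed(23)
  for (rep in 1:10) {
    true <- random_bl_tree(4)
    d <- oracle_patristic(true)
    nj <- neighbor_joining(d)
    # exhaustive quartet oracle: least-squares fit of the 3 topologies
    tips <- rownames(d)
    quartets <- list(
      c(1, 2, 3, 4), # (12|34)
      c(1, 3, 2, 4), # (13|24)
      c(1, 4, 2, 3) # (14|23)
    )
    ss <- vapply(quartets, function(q) {
      nwk <- sprintf(
        "((%s:1,%s:1):1,(%s:1,%s:1):1);",
        tips[q[1]], tips[q[2]], tips[q[3]], tips[q[4]]
      )
      topo <- ape::read.tree(text = nwk)
      # least squares: project d onto the topology's path space
      X <- do.call(rbind, lapply(combn(4, 2, simplify = FALSE), function(pr) {
        path <- ape::nodepath(topo, pr[1], pr[2])
        edges <- vapply(
          seq_len(length(path) - 1),
          function(k) {
            which((topo$edge[, 1] == path[k] & topo$edge[, 2] == path[k + 1]) |
              (topo$edge[, 1] == path[k + 1] & topo$edge[, 2] == path[k]))
          }, integer(1)
        )
        tabulate(edges, nbins = nrow(topo$edge))
      }))
      y <- apply(combn(4, 2), 2, function(pr) d[tips[pr[1]], tips[pr[2]]])
      fit <- lm.fit(X, y)
      sum(fit$residuals^2)
    }, numeric(1))
    best <- quartets[[which.min(ss)]]
    key_best <- paste(sort(tips[best[1:2]]), collapse = "|")
    ref <- sort(tips)[1]
    if (ref %in% tips[best[1:2]]) key_best <- paste(sort(tips[best[3:4]]), collapse = "|")
    expect_equal(tree_bipartitions(nj), key_best)
  }

  # independent cross-check against ape's NJ on a random alignment
  set.seed(24)
  aln <- annotated_alignment(random_alignment(8, 2000, gap_prob = 0), circular = FALSE)
  d <- pairwise_distance(aln, "p")
  mine <- neighbor_joining(d)
  apes <- ape::nj(as.dist(d))
  expect_setequal(tree_bipartitions(mine), tree_bipartitions(apes))
})

test_that("outgroup rooting preserves splits and ingroup path lengths", {
  set.seed(25)
  tr <- random_bl_tree(7)
  og <- tr$tip.label[1]
  rt <- root_with_outgroup(tr, og)
  expect_true(ape::is.rooted(rt))
  expect_setequal(tree_bipartitions(ape::unroot(rt)), tree_bipartitions(tr))

  ing <- setdiff(tr$tip.label, og)
  expect_equal(
    patristic_matrix(rt)[ing, ing],
    patristic_matrix(tr)[ing, ing],
    tolerance = 1e-12
  )

  tri <- neighbor_joining(oracle_patristic(random_bl_tree(3)))
  rt3 <- root_with_outgroup(tri, tri$tip.label[3])
  kids <- oracle_tips_below(rt3, length(rt3$tip.label) + 1L)
  expect_setequal(kids, rt3$tip.label)
  expect_error(root_with_outgroup(tr, "missing_tip"), "not in tree")
})

test_that("bootstrap supports are deterministic, bounded and auditable", {
  set.seed(26)
  aln <- annotated_alignment(random_alignment(6, 400, gap_prob = 0), circular = FALSE)
  b1 <- bootstrap_support(aln, "p", n_reps = 30, seed = 99, keep_replicates = TRUE)
  b2 <- bootstrap_support(aln, "p", n_reps = 30, seed = 99)
  expect_identical(b1$node.label, b2$node.label)
  sup <- b1$node.label[!is.na(b1$node.label)]
  expect_true(all(sup >= 0 & sup <= 1))

  # point-estimate topology does not depend on the bootstrap seed
  b3 <- bootstrap_support(aln, "p", n_reps = 5, seed = 1)
  expect_setequal(tree_bipartitions(b3), tree_bipartitions(b1))

  # recount supports from the stored replicate split sets
  reps <- attr(b1, "replicate_splits")
  keys <- tree_bipartitions(b1)
  for (k in keys) {
    recount <- mean(vapply(reps, function(s) k %in% s, logical(1)))
    nt <- length(b1$tip.label)
    node_ids <- names(mitomarker:::node_bipartition_keys(b1, named = TRUE))
    key_map <- mitomarker:::node_bipartition_keys(b1, named = TRUE)
    nd <- as.integer(node_ids[key_map == k])
    expect_equal(b1$node.label[nd - nt], recount)
  }

  # a single repeated column pattern makes every replicate identical
  pat <- c("A", "A", "C", "C", "G")
  m <- matrix(rep(pat, 50), nrow = 5, dimnames = list(paste0("t", 1:5), NULL))
  mono <- annotated_alignment(m, circular = FALSE)
  bm <- bootstrap_support(mono, "p", n_reps = 20, seed = 3)
  expect_true(all(bm$node.label[!is.na(bm$node.label)] == 1))
})
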