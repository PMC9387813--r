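# small circular toy used throughout: 60 columns, 6 taxa
make_toy <- function(seed = 1, features = NULL) {
  set.seed(seed)
  m <- random_alignment(6, 60, gap_prob = 0.03)
  annotated_alignment(m, features = features, circular = TRUE)
}

toy_features <- feature_table(
  name = c("a", "v", "b", "w"),
  class = c("cds", "dloop", "cds", "igr"),
  start = c(0L, 15L, 30L, 45L),
  end = c(10L, 20L, 40L, 50L),
  strand = c("+", "+", "+", "+")
)

test_that("rotation to an anchor gene is exact, invertible and H-preserving", {
  aln <- make_toy(features = toy_features)

  # anchor already at 0: identity
  expect_identical(normalize_start(aln, "a"), aln)

  rot <- normalize_start(aln, "b")
  expect_equal(aln_features(rot)$start[aln_features(rot)$name == "b"], 0L)
  # inverse composition restores the original
  back <- normalize_start(rot, "a")
  expect_identical(aln_matrix(back), aln_matrix(aln))
  expect_equal(as.data.frame(aln_features(back)), as.data.frame(aln_features(aln)))

  # H multiset is rotation invariant
  expect_equal(
    sort(heterogeneity_track(rot)$H),
    sort(heterogeneity_track(aln)$H)
  )
  # and so are full-genome pairwise distances
  d0 <- pairwise_distance(aln, "p")
  d1 <- pairwise_distance(rot, "p")
  expect_equal(d1[rownames(d0), colnames(d0)], d0)

  expect_error(normalize_start(aln, "nope"), "unknown anchor")
})

test_that("feature extraction handles width, origin wrap and minus strand", {
  f <- feature_table(
    c("in", "wrap", "neg"), c("cds", "cds", "cds"),
    c(10L, 90L, 20L), c(20L, 110L, 30L), c("+", "+", "-")
  )
  set.seed(2)
  aln <- annotated_alignment(random_alignment(4, 100, gap_prob = 0.1),
    features = f, circular = TRUE
  )
  expect_equal(aln_ncol(extract_feature(aln, "in")), 10L)

  wr <- extract_feature(aln, "wrap")
  expect_equal(aln_ncol(wr), 20L)
  expect_identical(
    aln_matrix(wr),
    aln_matrix(aln)[, c(91:100, 1:10)],
    ignore_attr = TRUE
  )

  # minus strand: reverse complement, gaps preserved (character-map oracle)
  neg <- extract_feature(aln, "neg")
  comp <- c(A = "T", C = "G", G = "C", T = "A", "-" = "-")
  plus <- aln_matrix(aln)[, 21:30]
  oracle <- t(apply(plus, 1, function(row) unname(comp[rev(row)])))
  expect_identical(unname(aln_matrix(neg)), unname(oracle))

  expect_error(extract_feature(aln, "nope"), "unknown gene")
})

test_that("segment extraction picks the arc containing the via anchor", {
  aln <- make_toy(features = toy_features)

  # a..b forward arc contains v
  seg <- extract_segment(aln, segment_spec("a", "b", via = "v"))
  expect_equal(aln_ncol(seg), 40L)
  expect_true(all(c("a", "v", "b") %in% aln_features(seg)$name))
  expect_false("w" %in% aln_features(seg)$name)

  # the other arc must be chosen when it is the one holding the anchor
  seg2 <- extract_segment(aln, segment_spec("b", "a", via = "w"))
  expect_true(all(c("b", "w", "a") %in% aln_features(seg2)$name))
  expect_false("v" %in% aln_features(seg2)$name)
  expect_equal(aln_ncol(seg2), 40L) # cols 30..59 then 0..9

  # segment columns equal the brute-force membership count
  len <- aln_ncol(aln)
  cols_of <- function(s, e) (seq.int(s, e - 1) %% len)
  arc <- cols_of(30, 70)
  members <- unique(c(cols_of(30, 40), cols_of(45, 50), cols_of(0, 10)))
  expect_true(all(members %in% arc))
  expect_equal(aln_ncol(seg2), length(arc))

  # via straddling a terminal boundary: no feasible arc
  bad <- annotated_alignment(aln_matrix(aln),
    features = feature_table(
      c("a", "b", "x"), c("cds", "cds", "igr"),
      c(0L, 20L, 5L), c(10L, 30L, 45L), "+"
    ),
    circular = TRUE
  )
  expect_error(extract_segment(bad, segment_spec("a", "b", via = "x")), "no contiguous arc")
})

test_that("gap-rich column masking removes and remaps consistently", {
  m <- rbind(
    s1 = c("A", "A", "-", "A", "-", "A"),
    s2 = c("A", "C", "-", "A", "A", "-"),
    s3 = c("A", "C", "A", "A", "-", "A")
  )
  aln <- annotated_alignment(m,
    features = feature_table("g", "cds", 1L, 5L),
    circular = FALSE
  )
  expect_equal(aln_ncol(mask_columns(aln, 1.0)), 6L) # vacuous

  masked <- mask_columns(aln, 0)
  rep <- attr(masked, "mask_report")
  expect_equal(rep$removed, 3L) # exactly the 3 gap-containing columns
  expect_equal(rep$removed + rep$retained, 6L)
  # feature [1,5) keeps columns {1, 3} -> remapped to [1, 3)
  f <- aln_features(masked)
  expect_equal(c(f$start, f$end), c(1L, 3L))
  expect_identical(
    unname(aln_matrix(masked)),
    unname(aln_matrix(aln)[, c(1, 2, 4)])
  )
})

test_that("concatenation preserves columns, lengths and distances", {
  aln <- make_toy(features = toy_features)
  expect_identical(concat_alignments(aln), aln)

  ga <- extract_feature(aln, "a")
  gb <- extract_feature(aln, "b")
  cc <- concat_alignments(ga, gb)
  expect_equal(aln_ncol(cc), 20L)

  # distances on the concatenation equal distances on the column union
  union_aln <- annotated_alignment(
    cbind(aln_matrix(ga), aln_matrix(gb)),
    circular = FALSE
  )
  expect_equal(pairwise_distance(cc, "p"), pairwise_distance(union_aln, "p"))

  shuffled <- annotated_alignment(aln_matrix(gb)[rev(seq_len(6)), ], circular = FALSE)
  expect_error(concat_alignments(ga, shuffled), "taxa")
})

test_that("extracting every feature in order and concatenating recovers the genome", {
  cfg <- sim_config(n_taxa = 5, seed = 3)
  bundle <- simulate_mito_dataset(cfg)
  aln <- bundle$alignment
  f <- aln_features(aln)
  f <- f[order(f$start), ]
  # use plus-strand extraction for all features to keep column order
  pieces <- lapply(f$name, function(nm) {
    ff <- f[f$name == nm, ]
    cols <- seq.int(ff$start, ff$end - 1L) + 1L
    annotated_alignment(aln_matrix(aln)[, cols, drop = FALSE], circular = FALSE)
  })
  expect_identical(aln_matrix(concat_alignments(pieces)), aln_matrix(aln))
})
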