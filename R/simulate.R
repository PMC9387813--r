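#' Configuration for the mitogenome population simulator
#'
#' The simulator emulates the statistical shape of intraspecific vertebrate
#' mitogenome datasets: a ~16.5 kb circular genome with the canonical gene
#' order (13 protein-coding genes, 2 rRNAs, 22 tRNAs, one control region),
#' conserved coding regions, and a hypervariable D-loop where both the
#' substitution rate and the indels concentrate. The genealogy is known, so
#' every downstream statistic can be checked against truth.
#'
#' `region_rates` are multiplicative factors applied on top of `base_rate`
#' per feature class; the defaults make the D-loop evolve 20x faster than
#' coding sequence. `base_rate` is the expected number of substitutions per
#' site from root to tip for a class with multiplier 1 (trees from
#' [sample_tree()] are scaled to unit depth).
#'
#' @param n_taxa Number of ingroup individuals (>= 3).
#' @param genome_length Circular genome length in bp.
#' @param region_rates Named non-negative multipliers for classes
#'   `cds`, `rrna`, `trna`, `dloop`, `igr`.
#' @param base_rate Root-to-tip expected substitutions/site at multiplier 1.
#' @param tree_model `"yule"` or `"coalescent"`.
#' @param indel_rate_dloop Expected gap patches per D-loop site (Poisson).
#' @param outgroup Simulate one extra lineage attached below the ingroup
#'   root, for outgroup rooting?
#' @param outgroup_depth Root-to-tip depth of the outgroup lineage, in units
#'   of the (unit) ingroup tree depth.
#' @param seed Integer seed; identical config + seed gives identical output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_taxa = 30L,
                       genome_length = 16500L,
                       region_rates = c(cds = 1, rrna = 0.6, trna = 0.4, dloop = 20, igr = 2),
                       base_rate = 0.03,
                       tree_model = c("yule", "coalescent"),
                       indel_rate_dloop = 0.01,
                       outgroup = TRUE,
                       outgroup_depth = 1.5,
                       seed = 1L) {
  tree_model <- match.arg(tree_model)
  if (n_taxa < 3) abort("n_taxa must be >= 3")
  if (genome_length <= 0) abort("genome_length must be positive")
  miss <- setdiff(FEATURE_CLASSES, names(region_rates))
  if (length(miss)) abort(paste0("region_rates missing class: ", paste(miss, collapse = ", ")))
  if (any(region_rates < 0)) abort("region rate multipliers must be >= 0")
  if (base_rate < 0) abort("base_rate must be >= 0")
  if (indel_rate_dloop < 0) abort("indel_rate_dloop must be >= 0")
  structure(
    list(
      n_taxa = as.integer(n_taxa), genome_length = as.integer(genome_length),
      region_rates = region_rates[FEATURE_CLASSES], base_rate = base_rate,
      tree_model = tree_model, indel_rate_dloop = indel_rate_dloop,
      outgroup = isTRUE(outgroup), outgroup_depth = outgroup_depth,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Sample a random genealogy
#'
#' Draws a binary tree under a pure-birth (Yule) or standard coalescent
#' model and rescales it to unit root-to-tip depth, so branch lengths are
#' fractions of the total divergence set later by `base_rate`.
#'
#' @param n_taxa Number of tips (>= 3).
#' @param tree_model `"yule"` or `"coalescent"`.
#' @param seed Integer seed.
#' @return An `ape::phylo` tree with tips `t01, t02, ...` and strictly
#'   positive branch lengths.
#' @export
sample_tree <- function(n_taxa, tree_model = c("yule", "coalescent"), seed = 1L) {
  tree_model <- match.arg(tree_model)
  if (n_taxa < 3) abort("n_taxa must be >= 3")
  set.seed(as.integer(seed))
  tr <- switch(tree_model,
    yule = ape::rphylo(n_taxa, birth = 1, death = 0),
    coalescent = ape::rcoal(n_taxa)
  )
  tr$tip.label <- sprintf("t%02d", seq_len(n_taxa))
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length / depth
  # degenerate zero-length branches would break "strictly positive"
  tr$edge.length <- pmax(tr$edge.length, 1e-9)
  tr
}

# Graft an outgroup lineage below the root: the ingroup (unit-depth) clade
# hangs on a stem of length (outgroup_depth - 1), the outgroup tip on a
# pendant branch of length outgroup_depth, keeping the tree ultrametric.
add_outgroup <- function(tree, label = "outgroup", outgroup_depth = 1.5) {
  if (outgroup_depth <= 1) abort("outgroup_depth must exceed the unit ingroup depth")
  stem <- outgroup_depth - 1
  core <- ape::write.tree(tree)
  core <- sub(";$", "", core)
  ape::read.tree(text = sprintf("(%s:%.10f,%s:%.10f);", core, stem, label, outgroup_depth))
}

# Canonical vertebrate mitogenome gene order (heavy-strand sense), with
# approximate gene lengths; igr spacers absorb whatever the configured
# genome length leaves over.
template_layout <- function() {
  tibble::tribble(
    ~name, ~class, ~len, ~strand,
    "trnF", "trna", 70L, "+",
    "rnS", "rrna", 950L, "+",
    "trnV", "trna", 70L, "+",
    "rnL", "rrna", 1510L, "+",
    "trnL2", "trna", 72L, "+",
    "nad1", "cds", 960L, "+",
    "trnI", "trna", 70L, "+",
    "trnQ", "trna", 72L, "-",
    "trnM", "trna", 70L, "+",
    "nad2", "cds", 1040L, "+",
    "trnW", "trna", 70L, "+",
    "trnA", "trna", 68L, "-",
    "trnN", "trna", 72L, "-",
    "trnC", "trna", 66L, "-",
    "trnY", "trna", 70L, "-",
    "cox1", "cds", 1540L, "+",
    "trnS2", "trna", 72L, "-",
    "trnD", "trna", 68L, "+",
    "cox2", "cds", 690L, "+",
    "trnK", "trna", 70L, "+",
    "atp8", "cds", 165L, "+",
    "atp6", "cds", 680L, "+",
    "cox3", "cds", 780L, "+",
    "trnG", "trna", 70L, "+",
    "nad3", "cds", 345L, "+",
    "trnR", "trna", 68L, "+",
    "nad4l", "cds", 295L, "+",
    "nad4", "cds", 1380L, "+",
    "trnH", "trna", 70L, "+",
    "trnS1", "trna", 66L, "+",
    "trnL1", "trna", 72L, "+",
    "nad5", "cds", 1740L, "+",
    "nad6", "cds", 525L, "-",
    "trnE", "trna", 70L, "-",
    "cob", "cds", 1140L, "+",
    "trnT", "trna", 70L, "+",
    "trnP", "trna", 68L, "-",
    "dloop", "dloop", 1210L, "+"
  )
}

#' Build the synthetic mitogenome annotation
#'
#' Lays the canonical vertebrate gene order on a circle of the configured
#' length: `trnF, rnS, trnV, rnL, ... , cob, trnT, trnP, dloop`, so that the
#' arc `cob -> dloop -> rnS` runs through the origin exactly as in
#' vertebrate mitogenomes. Leftover length is distributed as small `igr`
#' spacers at fixed positions away from that arc; features never overlap
#' and together with the spacers tile the genome exactly.
#'
#' @param config A [sim_config()] (only `genome_length` is used), or an
#'   integer genome length.
#' @return A feature tibble (see [feature_table()]).
#' @export
build_genome_template <- function(config = sim_config()) {
  len <- if (inherits(config, "sim_config")) config$genome_length else as.integer(config)
  lay <- template_layout()
  base <- sum(lay$len)
  if (len < base) {
    abort(sprintf("genome_length %d too small for the canonical feature set (%d bp)", len, base))
  }
  extra <- len - base
  if (extra > 0) {
    hosts <- c("trnQ", "trnN", "trnG", "nad4") # spacer insertion points
    sizes <- rep(extra %/% length(hosts), length(hosts))
    sizes[1] <- sizes[1] + extra %% length(hosts)
    keep <- sizes > 0
    spacers <- tibble(
      name = paste0("igr", seq_along(hosts))[keep], class = "igr",
      len = as.integer(sizes[keep]), strand = "+"
    )
    pieces <- vector("list", nrow(lay))
    for (i in seq_len(nrow(lay))) {
      pieces[[i]] <- lay[i, ]
      j <- match(lay$name[i], hosts)
      if (!is.na(j) && keep[j]) pieces[[i]] <- dplyr::bind_rows(lay[i, ], spacers[match(paste0("igr", j), spacers$name), ])
    }
    lay <- dplyr::bind_rows(pieces)
  }
  ends <- cumsum(lay$len)
  out <- feature_table(
    name = lay$name, class = lay$class,
    start = c(0L, head(ends, -1L)), end = ends, strand = lay$strand
  )
  validate_features(out, len)
  out
}

#' Evolve an alignment along a genealogy
#'
#' Simulates site-independent Jukes-Cantor substitution along the tree. The
#' per-site substitution scale is `branch length x base_rate x class
#' multiplier`, where the class is taken from the annotation (`igr` for any
#' unannotated column). The root sequence is uniform over `A C G T`.
#' Indels are restricted to the D-loop: Poisson-many gap patches, each a
#' short run of columns gapped in a random proper subset of taxa, so the
#' output stays a rectangular "aligned" matrix.
#'
#' @param tree An `ape::phylo` with branch lengths on the unit-depth scale
#'   (e.g. from [sample_tree()], optionally with an outgroup grafted).
#' @param template Feature tibble from [build_genome_template()].
#' @param config A [sim_config()].
#' @return A `truth_bundle`: list with `true_tree`, `alignment`
#'   (an [annotated_alignment()]), `per_site_rates`, `outgroup`, `config`.
#' @export
evolve_alignment <- function(tree, template, config = sim_config()) {
  if (any(config$region_rates < 0) || config$base_rate < 0) {
    abort("rates must be non-negative")
  }
  len <- config$genome_length
  site_class <- rep("igr", len)
  for (i in seq_len(nrow(template))) {
    site_class[feature_columns(template[i, ], len)] <- template$class[i]
  }
  per_site_rates <- config$base_rate * unname(config$region_rates[site_class])

  set.seed(config$seed + 1L)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  seqs <- matrix(NA_integer_, nrow = nnode, ncol = len)
  seqs[root, ] <- sample.int(4L, len, replace = TRUE) - 1L

  po <- ape::reorder.phylo(tree, "postorder")
  edges <- po$edge[rev(seq_len(nrow(po$edge))), , drop = FALSE] # preorder
  elens <- po$edge.length[rev(seq_len(nrow(po$edge)))]
  for (k in seq_len(nrow(edges))) {
    parent <- edges[k, 1L]
    child <- edges[k, 2L]
    t_site <- elens[k] * per_site_rates
    p_change <- 0.75 * (1 - exp(-4 / 3 * t_site))
    mut <- runif(len) < p_change
    s <- seqs[parent, ]
    if (any(mut)) {
      s[mut] <- (s[mut] + sample.int(3L, sum(mut), replace = TRUE)) %% 4L
    }
    seqs[child, ] <- s
  }

  m <- matrix(c("A", "C", "G", "T")[seqs[seq_len(ntip), , drop = FALSE] + 1L],
    nrow = ntip
  )
  rownames(m) <- tree$tip.label

  dl <- template[template$class == "dloop", ]
  if (nrow(dl) == 1 && config$indel_rate_dloop > 0) {
    cols <- feature_columns(dl[1, ], len)
    n_events <- rpois(1, config$indel_rate_dloop * length(cols))
    for (e in seq_len(n_events)) {
      w <- 1L + rgeom(1, 1 / 3) # mean-3 patch width
      at <- sample.int(length(cols) - min(w, length(cols)) + 1L, 1L)
      patch <- cols[at:min(at + w - 1L, length(cols))]
      k <- sample.int(ntip - 1L, 1L)
      rows <- sample.int(ntip, k)
      m[rows, patch] <- "-"
    }
  }

  og <- if (config$outgroup && "outgroup" %in% tree$tip.label) "outgroup" else NA_character_
  structure(
    list(
      true_tree = tree,
      alignment = annotated_alignment(m, features = template, circular = TRUE),
      per_site_rates = per_site_rates,
      outgroup = og,
      config = config
    ),
    class = "truth_bundle"
  )
}

#' Simulate a complete mitogenome population dataset
#'
#' Convenience wrapper: samples the genealogy, grafts the outgroup lineage
#' (if configured), builds the genome template and evolves the alignment.
#'
#' @param config A [sim_config()].
#' @return A `truth_bundle` (see [evolve_alignment()]).
#' @examples
#' bundle <- simulate_mito_dataset(sim_config(n_taxa = 5, genome_length = 16500))
#' bundle$alignment
#' @export
simulate_mito_dataset <- function(config = sim_config()) {
  tree <- sample_tree(config$n_taxa, config$tree_model, seed = config$seed)
  if (config$outgroup) tree <- add_outgroup(tree, outgroup_depth = config$outgroup_depth)
  template <- build_genome_template(config)
  evolve_alignment(tree, template, config)
}

#' Write / read a simulated dataset
#'
#' Serializes a truth bundle as plain text: aligned multi-FASTA, BED6+1
#' annotation, Newick true tree and a JSON echo of the configuration. The
#' files round-trip losslessly through the package's readers.
#'
#' @param bundle A `truth_bundle`.
#' @param dir Output directory (created if needed).
#' @return `write_dataset()` returns `dir` invisibly; `read_dataset()`
#'   returns a list with `alignment`, `true_tree`, `outgroup`, `config`.
#' @export
write_dataset <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  aln <- bundle$alignment
  write_alignment_fasta(aln, file.path(dir, "alignment.fasta"))
  write_features_bed(aln$features, file.path(dir, "features.bed"), aln_ncol(aln))
  ape::write.tree(bundle$true_tree, file.path(dir, "true_tree.nwk"))
  cfg <- unclass(bundle$config)
  cfg$outgroup_label <- bundle$outgroup
  jsonlite::write_json(cfg, file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  cfg <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  feats <- read_features_bed(file.path(dir, "features.bed"), cfg$genome_length)
  aln <- read_alignment_fasta(file.path(dir, "alignment.fasta"),
    features = feats, circular = TRUE
  )
  list(
    alignment = aln,
    true_tree = ape::read.tree(file.path(dir, "true_tree.nwk")),
    outgroup = cfg$outgroup_label,
    config = cfg
  )
}
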