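#' Rotate a circular alignment so a gene starts at column 0
#'
#' Circular genomes deposited with arbitrary start positions must be put on
#' a common coordinate frame before columns can be compared; this rotates
#' the columns (and all feature coordinates) so that `anchor_gene` begins at
#' column 0. The column multiset, and hence every per-column statistic, is
#' unchanged.
#'
#' @param aln A circular [annotated_alignment()].
#' @param anchor_gene Name of an annotated feature.
#' @return The rotated `annotated_alignment`.
#' @export
normalize_start <- function(aln, anchor_gene) {
  if (!aln$circular) abort("normalize_start() requires a circular alignment")
  f <- aln$features
  i <- match(anchor_gene, f$name)
  if (is.na(i)) abort(paste0("unknown anchor gene: ", anchor_gene))
  len <- aln_ncol(aln)
  k <- f$start[i] %% len
  if (k == 0L) {
    return(aln)
  }
  idx <- c((k + 1L):len, 1L:k)
  m <- aln$seqs[, idx, drop = FALSE]
  f$start <- (f$start - k) %% len
  f$end <- f$start + (aln$features$end - aln$features$start)
  annotated_alignment(m, features = f, circular = TRUE)
}

complement_chars <- function(v) {
  chartr("ACGT", "TGCA", v)
}

#' Excise a single annotated feature
#'
#' Returns the sub-alignment of exactly the feature's columns. Features
#' wrapping the circular origin (`end > length`) are handled modulo the
#' length; minus-strand features are returned reverse-complemented with
#' gaps preserved.
#'
#' @param aln An [annotated_alignment()].
#' @param gene_name Name of an annotated feature.
#' @return A linear `annotated_alignment` carrying the single feature at
#'   `[0, width)` on the plus strand.
#' @export
extract_feature <- function(aln, gene_name) {
  f <- aln$features
  i <- match(gene_name, f$name)
  if (is.na(i)) abort(paste0("unknown gene: ", gene_name))
  cols <- feature_columns(f[i, ], aln_ncol(aln))
  m <- aln$seqs[, cols, drop = FALSE]
  if (f$strand[i] == "-") {
    m <- m[, rev(seq_len(ncol(m))), drop = FALSE]
    m[] <- complement_chars(m)
  }
  annotated_alignment(
    m,
    features = feature_table(f$name[i], f$class[i], 0L, length(cols), "+"),
    circular = FALSE
  )
}

#' Define a contiguous multi-gene segment
#'
#' A segment runs along the circular genome from one terminal gene to
#' another; of the two candidate arcs between the terminals, the one
#' containing the `via` anchor (by default the D-loop) is taken. Both
#' terminal genes are included whole.
#'
#' @param terminal_a,terminal_b Names of the terminal genes.
#' @param via Name of the feature the arc must contain.
#' @param label Display label (default `"a-b"`).
#' @return A `segment_spec`.
#' @export
segment_spec <- function(terminal_a, terminal_b, via = "dloop", label = NULL) {
  if (identical(terminal_a, terminal_b)) abort("segment terminals must differ")
  structure(
    list(
      terminal_a = terminal_a, terminal_b = terminal_b, via = via,
      label = label %||% paste0(terminal_a, "-", terminal_b)
    ),
    class = "segment_spec"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Columns (1-based, in arc order) of the arc from feature a's first column
# forward (circularly) to feature b's last column.
arc_columns <- function(fa, fb, len) {
  span <- (fb$end - 1L - fa$start) %% len + 1L
  interval_columns(fa$start, fa$start + span, len)
}

#' Excise a contiguous segment spanning between two genes
#'
#' @param aln A circular [annotated_alignment()].
#' @param spec A [segment_spec()].
#' @return A linear `annotated_alignment` of the chosen arc, with all
#'   features fully contained in the arc remapped onto it.
#' @export
extract_segment <- function(aln, spec) {
  f <- aln$features
  len <- aln_ncol(aln)
  for (nm in c(spec$terminal_a, spec$terminal_b, spec$via)) {
    if (!nm %in% f$name) abort(paste0("unknown feature in segment spec: ", nm))
  }
  fa <- f[f$name == spec$terminal_a, ]
  fb <- f[f$name == spec$terminal_b, ]
  fv <- f[f$name == spec$via, ]
  cand <- list(
    arc_columns(fa, fb, len), # a ... b
    arc_columns(fb, fa, len) # b ... a
  )
  contains <- function(cols, feat) all(feature_columns(feat, len) %in% cols)
  ok <- vapply(cand, function(cols) {
    contains(cols, fa) && contains(cols, fb) && contains(cols, fv)
  }, logical(1))
  if (!any(ok)) {
    abort(sprintf(
      "no contiguous arc contains %s, %s and %s entirely",
      spec$terminal_a, spec$terminal_b, spec$via
    ))
  }
  cols <- cand[[which(ok)[1]]]
  m <- aln$seqs[, cols, drop = FALSE]
  # remap features wholly inside the arc onto segment coordinates
  pos_in_arc <- match(seq_len(len), cols) # 1-based position or NA
  kept <- list()
  for (i in seq_len(nrow(f))) {
    fc <- feature_columns(f[i, ], len)
    at <- pos_in_arc[fc]
    if (anyNA(at)) next
    # contiguity in arc coordinates is guaranteed for contained features
    kept[[length(kept) + 1L]] <- feature_table(
      f$name[i], f$class[i], min(at) - 1L, max(at), f$strand[i]
    )
  }
  out <- annotated_alignment(m,
    features = if (length(kept)) dplyr::bind_rows(kept) else NULL,
    circular = FALSE
  )
  attr(out, "segment_label") <- spec$label
  out
}

#' Drop gap-rich alignment columns
#'
#' A desk-scale column filter: removes every column whose gap fraction
#' exceeds `max_gap_fraction` and remaps feature coordinates onto the
#' retained-column index space (features losing all their columns are
#' dropped). Defaults effectively off (`max_gap_fraction = 1`).
#'
#' @param aln An [annotated_alignment()].
#' @param max_gap_fraction Columns with gap fraction strictly above this are
#'   removed; in `[0, 1]`.
#' @return The filtered alignment, with attribute `mask_report` (a tibble
#'   with `removed` and `retained` column counts).
#' @export
mask_columns <- function(aln, max_gap_fraction = 1) {
  if (max_gap_fraction < 0 || max_gap_fraction > 1) {
    abort("max_gap_fraction must be in [0, 1]")
  }
  len <- aln_ncol(aln)
  gap_frac <- colMeans(aln$seqs == "-")
  keep <- gap_frac <= max_gap_fraction
  kept_before <- c(0L, cumsum(keep)) # kept columns in [0, s)
  f <- aln$features
  rows <- list()
  for (i in seq_len(nrow(f))) {
    cols0 <- (seq.int(f$start[i], f$end[i] - 1L) %% len) # 0-based
    n_kept <- sum(keep[cols0 + 1L])
    if (n_kept == 0L) next
    new_start <- kept_before[(f$start[i] %% len) + 1L]
    rows[[length(rows) + 1L]] <- feature_table(
      f$name[i], f$class[i], new_start, new_start + n_kept, f$strand[i]
    )
  }
  out <- annotated_alignment(
    aln$seqs[, keep, drop = FALSE],
    features = if (length(rows)) dplyr::bind_rows(rows) else NULL,
    circular = aln$circular
  )
  attr(out, "mask_report") <- tibble(removed = sum(!keep), retained = sum(keep))
  out
}

#' Concatenate alignments column-wise
#'
#' All alignments must share the same taxa in the same order. Feature
#' coordinates are shifted by the running offset; duplicate feature names
#' across blocks are disambiguated with a numeric suffix.
#'
#' @param ... `annotated_alignment` objects (or a single list of them).
#' @return A linear `annotated_alignment` whose length is the sum of the
#'   input lengths.
#' @export
concat_alignments <- function(...) {
  alns <- list(...)
  if (length(alns) == 1 && !inherits(alns[[1]], "annotated_alignment")) {
    alns <- alns[[1]]
  }
  if (!length(alns)) abort("nothing to concatenate")
  taxa <- aln_taxa(alns[[1]])
  for (a in alns) {
    if (!identical(aln_taxa(a), taxa)) abort("taxa sets/orders differ between alignments")
  }
  if (length(alns) == 1) {
    return(alns[[1]])
  }
  m <- do.call(cbind, lapply(alns, aln_matrix))
  offs <- c(0L, cumsum(vapply(alns, aln_ncol, integer(1))))
  feats <- purrr::imap_dfr(alns, function(a, i) {
    f <- a$features
    if (!nrow(f)) {
      return(f)
    }
    f$start <- f$start + offs[[i]]
    f$end <- f$end + offs[[i]]
    f
  })
  if (nrow(feats) && anyDuplicated(feats$name)) {
    feats$name <- make.unique(feats$name, sep = ".")
  }
  annotated_alignment(m, features = feats, circular = FALSE)
}
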