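#' Annotated multiple sequence alignment on a (circular) genome
#'
#' The central container of the package: a character matrix of aligned
#' sequences (rows = taxa, columns = alignment positions, alphabet
#' `A C G T -`) together with a tibble of gene features on the alignment
#' coordinate system and a circularity flag. Coordinates are 0-based,
#' half-open; a feature whose `end` exceeds the alignment length wraps
#' through the origin (interpreted modulo the length).
#'
#' Ambiguity codes (N, W, M, R, ...) are rejected with an error: the
#' pipeline is defined for unambiguous sequence only, and silently masking
#' would distort the heterogeneity statistic, which treats the gap as a
#' fifth character class.
#'
#' @param seqs A character matrix with unique rownames (taxa), or a named
#'   character vector of equal-length aligned sequence strings.
#' @param features A tibble with columns `name`, `class`, `start`, `end`,
#'   `strand` (see [feature_table()]), or `NULL` for no annotation.
#' @param circular Logical; is the coordinate system circular?
#' @return An object of class `annotated_alignment`.
#' @examples
#' aln <- annotated_alignment(c(a = "ACGT", b = "ACGA"),
#'   features = feature_table("geneA", "cds", 0L, 4L)
#' )
#' aln_ncol(aln)
#' @export
annotated_alignment <- function(seqs, features = NULL, circular = TRUE) {
  m <- as_aln_matrix(seqs)
  if (is.null(features)) features <- empty_features()
  obj <- structure(
    list(seqs = m, features = as_tibble(features), circular = isTRUE(circular)),
    class = "annotated_alignment"
  )
  validate_alignment(obj)
}

as_aln_matrix <- function(seqs) {
  if (is.matrix(seqs)) {
    m <- toupper(seqs)
  } else if (is.character(seqs)) {
    if (is.null(names(seqs))) abort("sequence vector must be named by taxon")
    lens <- nchar(seqs)
    if (length(unique(lens)) > 1) abort("sequences are not aligned: unequal lengths")
    m <- do.call(rbind, strsplit(toupper(seqs), "", fixed = TRUE))
    rownames(m) <- names(seqs)
  } else {
    abort("`seqs` must be a character matrix or named character vector")
  }
  m
}

empty_features <- function() {
  tibble(
    name = character(), class = character(),
    start = integer(), end = integer(), strand = character()
  )
}

#' Build a gene feature table
#'
#' @param name,class,start,end,strand Vectors of equal length describing the
#'   features: `class` is one of `cds`, `rrna`, `trna`, `dloop`, `igr`;
#'   `start`/`end` are 0-based half-open alignment coordinates (`end` may
#'   exceed the alignment length to denote a wrap through the origin);
#'   `strand` is `"+"` or `"-"`.
#' @return A tibble with one row per feature.
#' @export
feature_table <- function(name, class, start, end, strand = "+") {
  tibble(
    name = as.character(name), class = as.character(class),
    start = as.integer(start), end = as.integer(end),
    strand = rep_len(as.character(strand), length(name))
  )
}

validate_features <- function(features, len) {
  f <- features
  stopifnot(all(c("name", "class", "start", "end", "strand") %in% names(f)))
  if (anyDuplicated(f$name)) abort("feature names must be unique")
  bad_class <- setdiff(unique(f$class), FEATURE_CLASSES)
  if (length(bad_class)) {
    abort(paste0("unknown feature class: ", paste(bad_class, collapse = ", ")))
  }
  if (nrow(f)) {
    if (any(f$start < 0 | f$start >= len)) abort("feature start out of range [0, length)")
    if (any(f$start >= f$end)) abort("feature start must be < end")
    if (any(f$end - f$start > len)) abort("feature longer than the alignment")
    if (!all(f$strand %in% c("+", "-"))) abort("strand must be '+' or '-'")
  }
  invisible(f)
}

validate_alignment <- function(x) {
  m <- x$seqs
  if (!is.matrix(m) || nrow(m) < 1) abort("alignment needs at least one sequence")
  if (is.null(rownames(m)) || anyDuplicated(rownames(m))) {
    abort("taxa (rownames) must be present and unique")
  }
  bad <- setdiff(unique(as.vector(m)), ALN_ALPHABET)
  if (length(bad)) {
    abort(paste0(
      "illegal characters in alignment (ambiguity codes are not accepted): ",
      paste(bad, collapse = ", ")
    ))
  }
  validate_features(x$features, ncol(m))
  x
}

#' @rdname annotated_alignment
#' @param x An `annotated_alignment`.
#' @export
aln_taxa <- function(x) rownames(x$seqs)

#' @rdname annotated_alignment
#' @export
aln_ncol <- function(x) ncol(x$seqs)

#' @rdname annotated_alignment
#' @export
aln_matrix <- function(x) x$seqs

#' @rdname annotated_alignment
#' @export
aln_features <- function(x) x$features

#' @export
print.annotated_alignment <- function(x, ...) {
  cat(sprintf(
    "<annotated_alignment> %d taxa x %d columns (%s)\n",
    nrow(x$seqs), ncol(x$seqs), if (x$circular) "circular" else "linear"
  ))
  if (nrow(x$features)) {
    cat(sprintf(
      "  %d features: %s\n", nrow(x$features),
      paste(head(x$features$name, 8), collapse = ", ")
    ))
  }
  invisible(x)
}

# Column indices (1-based, in arc order) covered by a 0-based half-open
# [start, end) interval on a circle of `len` columns.
interval_columns <- function(start, end, len) {
  (seq.int(start, end - 1L) %% len) + 1L
}

feature_columns <- function(feature, len) {
  interval_columns(feature$start, feature$end, len)
}

#' Read / write an aligned multi-FASTA
#'
#' Thin wrappers around Biostrings. The reader enforces the package
#' alphabet (ambiguity codes raise an error) and equal sequence lengths.
#'
#' @param path File path.
#' @param features Optional feature table to attach (see [feature_table()]).
#' @param circular Circularity flag for the returned alignment.
#' @return `read_alignment_fasta()` returns an `annotated_alignment`;
#'   `write_alignment_fasta()` returns `path` invisibly.
#' @export
read_alignment_fasta <- function(path, features = NULL, circular = TRUE) {
  ss <- Biostrings::readBStringSet(path)
  seqs <- setNames(toupper(as.character(ss)), names(ss))
  annotated_alignment(seqs, features = features, circular = circular)
}

#' @rdname read_alignment_fasta
#' @param aln An `annotated_alignment`.
#' @export
write_alignment_fasta <- function(aln, path) {
  seqs <- apply(aln$seqs, 1L, paste0, collapse = "")
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), filepath = path)
  invisible(path)
}

#' Read / write the feature annotation as BED
#'
#' BED6+1 dialect: 0-based half-open coordinates, the feature class carried
#' in a seventh column. A feature crossing the circular origin is split into
#' two BED lines sharing a name; the reader merges such pairs back into a
#' single wrapped feature (`end > genome_length`).
#'
#' @param features A feature table ([feature_table()]).
#' @param path File path.
#' @param genome_length Alignment length (needed to split/merge wraps).
#' @param chrom Sequence name written in column 1.
#' @return `read_features_bed()` returns a feature tibble;
#'   `write_features_bed()` returns `path` invisibly.
#' @export
write_features_bed <- function(features, path, genome_length, chrom = "mtDNA") {
  f <- features
  rows <- purrr::pmap_dfr(f, function(name, class, start, end, strand) {
    if (end <= genome_length) {
      tibble(start = start, end = end, name = name, strand = strand, class = class)
    } else {
      tibble(
        start = c(start, 0L), end = c(genome_length, end - genome_length),
        name = name, strand = strand, class = class
      )
    }
  })
  out <- tibble(
    chrom = chrom, start = rows$start, end = rows$end,
    name = rows$name, score = 0L, strand = rows$strand, class = rows$class
  )
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_features_bed
#' @export
read_features_bed <- function(path, genome_length) {
  cols <- c("chrom", "start", "end", "name", "score", "strand", "class")
  df <- readr::read_tsv(path,
    col_names = cols, show_col_types = FALSE,
    col_types = readr::cols(
      chrom = "c", start = "i", end = "i", name = "c",
      score = "i", strand = "c", class = "c"
    )
  )
  merged <- df |>
    dplyr::group_by(.data$name) |>
    dplyr::group_modify(function(g, key) {
      if (nrow(g) == 1) {
        return(g[, c("class", "start", "end", "strand")])
      }
      if (nrow(g) != 2) abort("a split feature must have exactly two BED lines")
      up <- g[g$end == genome_length, , drop = FALSE]
      dn <- g[g$start == 0L, , drop = FALSE]
      if (nrow(up) != 1 || nrow(dn) != 1) abort("split feature lines do not meet at the origin")
      tibble(
        class = up$class, start = up$start,
        end = genome_length + dn$end, strand = up$strand
      )
    }) |>
    dplyr::ungroup()
  # restore genomic order rather than the group_by alphabetical order
  merged <- merged[order(merged$start), c("name", "class", "start", "end", "strand")]
  validate_features(merged, genome_length)
  merged
}
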