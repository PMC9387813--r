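#' Per-column sequence heterogeneity
#'
#' The heterogeneity of an alignment column is
#' \deqn{H = 1 - \sum_i p_i^2, \quad i \in \{A, T, G, C, \mathrm{gap}\},}
#' where \eqn{p_i} is the frequency of character \eqn{i} in the column. The
#' gap counts as a fifth character class, so \eqn{H} ranges from 0
#' (monomorphic column) to \eqn{1 - 1/5 = 0.8} (all five classes equally
#' frequent).
#'
#' @param column A character vector of single characters, or a single
#'   string, over `A C G T -`.
#' @return The heterogeneity value, a number in `[0, 0.8]`.
#' @examples
#' column_heterogeneity("AATT") # 0.5
#' @export
column_heterogeneity <- function(column) {
  if (length(column) == 1 && nchar(column) > 1) {
    column <- strsplit(column, "", fixed = TRUE)[[1]]
  }
  if (!length(column)) abort("column must be non-empty")
  column <- toupper(column)
  bad <- setdiff(unique(column), ALN_ALPHABET)
  if (length(bad)) abort(paste0("illegal character in column: ", paste(bad, collapse = ", ")))
  counts <- vapply(ALN_ALPHABET, function(b) sum(column == b), numeric(1))
  n <- length(column)
  stopifnot(sum(counts) == n) # p_i sum to 1 exactly
  1 - sum(counts^2) / n^2
}

new_het_track <- function(position, H, window, step) {
  structure(
    tibble(position = as.integer(position), H = as.numeric(H)),
    window = as.integer(window), step = as.integer(step),
    class = c("het_track", class(tibble()))
  )
}

#' Heterogeneity profile of an alignment
#'
#' Computes one H value per alignment column (see
#' [column_heterogeneity()]), as a tibble track with 0-based positions.
#'
#' @param aln An [annotated_alignment()].
#' @return A `het_track` tibble with columns `position` and `H`
#'   (attributes `window = 1`, `step = 1`).
#' @export
heterogeneity_track <- function(aln) {
  m <- aln_matrix(aln)
  if (!ncol(m)) abort("empty alignment")
  n <- nrow(m)
  counts <- vapply(ALN_ALPHABET, function(b) colSums(m == b), numeric(ncol(m)))
  counts <- matrix(counts, ncol = length(ALN_ALPHABET))
  stopifnot(all(rowSums(counts) == n)) # every character accounted for
  H <- 1 - rowSums(counts^2) / n^2
  new_het_track(seq_len(ncol(m)) - 1L, H, 1L, 1L)
}

#' Sliding-window summary of a heterogeneity track
#'
#' Averages the raw per-column track in windows of `window` columns moved
#' by `step` (the conventional profile uses window 10, step 5). Trailing
#' partial windows are dropped; for circular genomes `circular = TRUE`
#' instead wraps windows through the origin so every start position is
#' summarized.
#'
#' @param track A raw `het_track` from [heterogeneity_track()].
#' @param window,step Window width and offset between window starts, in
#'   columns.
#' @param stat Summary within each window: `"mean"` (default) or `"max"`.
#' @param circular Wrap windows through the origin?
#' @return A `het_track` tibble; `position` holds window starts.
#' @export
sliding_window <- function(track, window = 10L, step = 5L,
                           stat = c("mean", "max"), circular = FALSE) {
  stat <- match.arg(stat)
  L <- nrow(track)
  if (window < 1 || step < 1) abort("window and step must be >= 1")
  if (window > L) abort("window larger than the track")
  fun <- if (stat == "mean") mean else max
  starts <- if (circular) {
    seq.int(0L, L - 1L, by = step)
  } else {
    seq.int(0L, L - window, by = step)
  }
  H <- vapply(starts, function(s) {
    idx <- (seq.int(s, s + window - 1L) %% L) + 1L
    fun(track$H[idx])
  }, numeric(1))
  new_het_track(starts, H, window, step)
}

#' Export / import a heterogeneity track
#'
#' TSV writes `position` (0-based) and `H`; bedGraph writes half-open
#' `[position, position + step)` intervals on a named sequence.
#'
#' @param track A `het_track`.
#' @param path Output path.
#' @param format `"tsv"` or `"bedgraph"`.
#' @param chrom Sequence name for bedGraph.
#' @return `export_track()` returns `path` invisibly; `read_track()`
#'   returns a `het_track`.
#' @export
export_track <- function(track, path, format = c("tsv", "bedgraph"), chrom = "mtDNA") {
  format <- match.arg(format)
  if (format == "tsv") {
    readr::write_tsv(tibble(position = track$position, H = track$H), path)
  } else {
    step <- attr(track, "step") %||% 1L
    df <- tibble(
      chrom = chrom, start = track$position,
      end = track$position + step, H = track$H
    )
    readr::write_tsv(df, path, col_names = FALSE)
  }
  invisible(path)
}

#' @rdname export_track
#' @export
read_track <- function(path, format = c("tsv", "bedgraph")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- readr::read_tsv(path, show_col_types = FALSE, col_types = "id")
    new_het_track(df$position, df$H, 1L, 1L)
  } else {
    df <- readr::read_tsv(path,
      col_names = c("chrom", "start", "end", "H"),
      show_col_types = FALSE, col_types = "ciid"
    )
    step <- if (nrow(df)) df$end[1] - df$start[1] else 1L
    new_het_track(df$start, df$H, step, step)
  }
}

#' Plot a heterogeneity track
#'
#' @param object A `het_track`.
#' @param features Optional feature tibble; D-loop extents are shaded.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot het_track
#' @export
autoplot.het_track <- function(object, features = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$position, y = .data$H)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "alignment position (bp)", y = "heterogeneity H") +
    ggplot2::ylim(0, 0.8) +
    ggplot2::theme_minimal()
  if (!is.null(features)) {
    dl <- features[features$class == "dloop", ]
    if (nrow(dl)) {
      p <- p + ggplot2::annotate("rect",
        xmin = dl$start, xmax = dl$end, ymin = 0, ymax = 0.8,
        alpha = 0.15, fill = "firebrick"
      )
    }
  }
  p
}
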