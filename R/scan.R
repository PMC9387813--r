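#' The standard candidate-marker menu
#'
#' Enumerates the markers evaluated by the scan: the single genes `cob`
#' and `cox1`, the D-loop, the five contiguous spans through the control
#' region (`cob-cox1`, `cob-nad2`, `cob-nad1`, `cob-rnL`, `cob-rnS`, all
#' anchored `via = "dloop"`), and the full genome — nine specs in total.
#' Markers whose genes are missing from the annotation are skipped with a
#' warning.
#'
#' @param features A feature tibble ([feature_table()]).
#' @return A named list of marker specs: elements are either
#'   `list(type = "gene", name = )`, `list(type = "segment", spec = )`
#'   ([segment_spec()]), or `list(type = "full")`.
#' @export
default_segment_menu <- function(features) {
  have <- function(g) all(g %in% features$name)
  menu <- list()
  for (g in c("cob", "cox1", "dloop")) {
    if (have(g)) {
      menu[[g]] <- list(type = "gene", name = g)
    } else {
      warn(paste0("gene missing from annotation, marker skipped: ", g))
    }
  }
  partners <- c("cox1", "nad2", "nad1", "rnL", "rnS")
  for (p in partners) {
    lbl <- paste0("cob-", p)
    if (have(c("cob", p, "dloop"))) {
      menu[[lbl]] <- list(type = "segment", spec = segment_spec("cob", p, via = "dloop", label = lbl))
    } else {
      warn(paste0("gene missing from annotation, marker skipped: ", lbl))
    }
  }
  menu[["full_mtdna"]] <- list(type = "full")
  menu
}

extract_marker <- function(aln, marker) {
  switch(marker$type,
    gene = extract_feature(aln, marker$name),
    segment = extract_segment(aln, marker$spec),
    full = aln,
    abort("unknown marker type")
  )
}

#' Randomly subsample taxa for a scan replicate
#'
#' Draws `k` taxa uniformly without replacement, where `k` is
#' `k_override` if given and `round(fraction * n)` otherwise (e.g. 60% of
#' 115 taxa gives 69). The draw is deterministic in `(seed, replicate)`.
#'
#' @param taxa Character vector of taxon labels.
#' @param fraction Subsampling fraction in `(0, 1]`.
#' @param k_override Optional explicit subset size.
#' @param seed Integer seed.
#' @param replicate Replicate index (>= 1).
#' @return A character vector of `k` taxa (original order preserved).
#' @export
subsample_taxa <- function(taxa, fraction = 0.6, k_override = NULL,
                           seed = 1L, replicate = 1L) {
  n <- length(taxa)
  if (fraction <= 0 || fraction > 1) abort("fraction must be in (0, 1]")
  k <- if (!is.null(k_override)) as.integer(k_override) else as.integer(round(fraction * n))
  if (k < 4) abort("subsample size must be >= 4")
  if (k > n) abort("subsample size exceeds the number of taxa")
  set.seed(as.integer((as.integer(seed) + 99991 * as.integer(replicate)) %% 2147483647L))
  taxa[sort(sample.int(n, k))]
}

#' Configure a marker scan
#'
#' @param segments Marker list as from [default_segment_menu()], or `NULL`
#'   to build the default menu from the dataset's annotation.
#' @param subsample_fraction Fraction of ingroup taxa per replicate.
#' @param subsample_k Optional explicit subset size (overrides fraction).
#' @param n_replicates Number of subsampling replicates.
#' @param model Distance model for tree building (`"p"` or `"jc69"`); the
#'   p-distance default is robust to saturation in the hypervariable
#'   D-loop.
#' @param outgroup Optional outgroup tip: always included in subsamples
#'   and used to root the reference tree.
#' @param seed Integer seed governing all subsampling.
#' @return A `scan_config` list.
#' @export
scan_config <- function(segments = NULL, subsample_fraction = 0.6,
                        subsample_k = NULL, n_replicates = 50L,
                        model = c("p", "jc69"), outgroup = NULL, seed = 1L) {
  model <- match.arg(model)
  if (subsample_fraction <= 0 || subsample_fraction > 1) {
    abort("subsample_fraction must be in (0, 1]")
  }
  if (n_replicates < 1) abort("n_replicates must be >= 1")
  structure(
    list(
      segments = segments, subsample_fraction = subsample_fraction,
      subsample_k = subsample_k, n_replicates = as.integer(n_replicates),
      model = model, outgroup = outgroup, seed = as.integer(seed)
    ),
    class = "scan_config"
  )
}

#' Run the marker concordance scan
#'
#' The headline experiment: a reference tree is built from the full-length
#' alignment on all taxa; then, for each replicate, a random taxon subset
#' is drawn (shared by all markers in that replicate, so comparisons are
#' paired) and for each candidate marker a tree is built from the marker's
#' columns on those taxa. Each replicate tree is scored against the
#' reference by clade concordance and patristic-distance correlation
#' (after pruning to common tips). Markers failing in a replicate (e.g.
#' no comparable sites) yield `NA` for that replicate.
#'
#' @param aln A circular [annotated_alignment()] with annotation covering
#'   the menu genes.
#' @param config A [scan_config()].
#' @return A `concordance_report`: list with `results` (tibble: `segment`,
#'   `replicate`, `n_taxa`, `n_columns`, `concordance`, `pearson_r`,
#'   `spearman_rho`), `summary` (per-segment five-number summary),
#'   `manifests` (taxa drawn per replicate), `reference_tree`, `config`.
#' @export
run_scan <- function(aln, config = scan_config()) {
  menu <- config$segments %||% default_segment_menu(aln$features)
  taxa <- aln_taxa(aln)
  ingroup <- setdiff(taxa, config$outgroup)

  ref_tree <- suppressWarnings(neighbor_joining(pairwise_distance(aln, config$model)))
  if (!is.null(config$outgroup)) {
    ref_tree <- root_with_outgroup(ref_tree, config$outgroup)
  }

  marker_alns <- lapply(menu, function(mk) extract_marker(aln, mk))
  manifests <- lapply(seq_len(config$n_replicates), function(r) {
    sub <- subsample_taxa(ingroup,
      fraction = config$subsample_fraction,
      k_override = config$subsample_k,
      seed = config$seed, replicate = r
    )
    c(sub, config$outgroup)
  })

  rows <- list()
  for (r in seq_len(config$n_replicates)) {
    sub <- manifests[[r]]
    for (s in names(menu)) {
      sa <- marker_alns[[s]]
      sub_aln <- annotated_alignment(
        aln_matrix(sa)[sub, , drop = FALSE],
        circular = FALSE
      )
      res <- tryCatch(
        {
          # replicate builds routinely clamp the odd negative NJ branch;
          # per-call warnings would swamp the log at n_replicates scale
          tr <- suppressWarnings(
            neighbor_joining(pairwise_distance(sub_aln, config$model))
          )
          cc <- clade_concordance(ref_tree, tr)
          corr <- tree_distance_correlation(ref_tree, tr)
          list(cc = cc, pe = corr$pearson_r, sp = corr$spearman_rho)
        },
        error = function(e) list(cc = NA_real_, pe = NA_real_, sp = NA_real_)
      )
      rows[[length(rows) + 1L]] <- tibble(
        segment = s, replicate = r, n_taxa = length(sub),
        n_columns = aln_ncol(sa),
        concordance = res$cc, pearson_r = res$pe, spearman_rho = res$sp
      )
    }
  }
  results <- dplyr::bind_rows(rows)
  summary <- results |>
    dplyr::group_by(.data$segment) |>
    dplyr::summarise(
      n_columns = .data$n_columns[1],
      n = sum(!is.na(.data$concordance)),
      min = min(.data$concordance, na.rm = TRUE),
      q1 = quantile(.data$concordance, 0.25, na.rm = TRUE, names = FALSE),
      median = stats::median(.data$concordance, na.rm = TRUE),
      q3 = quantile(.data$concordance, 0.75, na.rm = TRUE, names = FALSE),
      max = max(.data$concordance, na.rm = TRUE),
      .groups = "drop"
    )
  structure(
    list(
      results = results, summary = summary, manifests = manifests,
      reference_tree = ref_tree, config = config
    ),
    class = "concordance_report"
  )
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf(
    "<concordance_report> %d markers x %d replicates\n",
    dplyr::n_distinct(x$results$segment), x$config$n_replicates
  ))
  print(x$summary, ...)
  invisible(x)
}

#' @rdname run_scan
#' @param x A `concordance_report`.
#' @param ... Unused.
#' @method tidy concordance_report
#' @export
tidy.concordance_report <- function(x, ...) x$results

#' @rdname run_scan
#' @method glance concordance_report
#' @export
glance.concordance_report <- function(x, ...) x$summary

#' Rank markers by median concordance
#'
#' Sorts markers by descending median concordance; at equal medians the
#' shorter marker ranks first (a shorter marker is preferable at equal
#' performance). Optionally adds one-sided Mann-Whitney U comparisons of
#' each marker's concordance distribution against the next-ranked one.
#'
#' @param report A `concordance_report` from [run_scan()].
#' @param test Add pairwise one-sided Mann-Whitney U tests?
#' @param p_adjust Multiplicity adjustment method for the pairwise table
#'   (see [stats::p.adjust()]); `"none"` by default.
#' @return A tibble `segment`, `n_columns`, `median_concordance`, `rank`;
#'   when `test = TRUE`, attribute `pairwise` holds a tibble of all
#'   ordered pairs with `statistic` (U) and `p_value` for the alternative
#'   "segment_a's concordance exceeds segment_b's".
#' @export
rank_segments <- function(report, test = FALSE, p_adjust = "none") {
  s <- report$summary
  if (nrow(s) < 2) abort("ranking needs at least two markers")
  ranked <- s[order(-s$median, s$n_columns), c("segment", "n_columns", "median")]
  names(ranked)[3] <- "median_concordance"
  ranked$rank <- seq_len(nrow(ranked))
  if (test) {
    segs <- ranked$segment
    pairs <- expand.grid(a = segs, b = segs, stringsAsFactors = FALSE)
    pairs <- pairs[pairs$a != pairs$b, ]
    pw <- purrr::pmap_dfr(pairs, function(a, b) {
      xa <- report$results$concordance[report$results$segment == a]
      xb <- report$results$concordance[report$results$segment == b]
      wt <- suppressWarnings(wilcox.test(xa, xb, alternative = "greater", exact = FALSE))
      tibble(
        segment_a = a, segment_b = b,
        statistic = unname(wt$statistic), p_value = wt$p.value
      )
    })
    pw$p_value <- stats::p.adjust(pw$p_value, method = p_adjust)
    attr(ranked, "pairwise") <- pw
  }
  ranked
}

#' Box-and-whisker plot of a concordance report
#'
#' @param object A `concordance_report`.
#' @param ... Unused.
#' @return A ggplot object: one box per marker, ordered by median
#'   concordance.
#' @method autoplot concordance_report
#' @export
autoplot.concordance_report <- function(object, ...) {
  df <- object$results
  ord <- object$summary$segment[order(object$summary$median)]
  df$segment <- factor(df$segment, levels = ord)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$segment, y = .data$concordance)) +
    ggplot2::geom_boxplot(fill = "steelblue", alpha = 0.6, outlier.size = 0.8) +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "clade concordance with the full-mtDNA tree"
    ) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
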