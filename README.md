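# mitomarker

Complete mitochondrial genomes often resolve intraspecific phylogenies
that traditional short markers — a single gene like *cob* or *cox1*, or
the hypervariable D-loop — distort or miss. `mitomarker` is for
molecular ecologists and phylogeneticists who want to know, for their
organism, **which contiguous piece of the mitogenome best reproduces
the full-genome phylogeny**, and in particular whether a compact
segment running through the control region (such as *cob*–*rnS*,
~3.5–4 kb) can stand in for the whole ~16.5 kb molecule in an
amplicon-based design.

## What it computes

* **Per-column heterogeneity** of an alignment,
  `H = 1 − Σ pᵢ², i ∈ {A, T, G, C, gap}` (gap is a fifth character
  class; `0 ≤ H ≤ 0.8`), with sliding-window smoothing (default
  window 10, step 5).
* **Circular-genome preparation**: rotation to a common start
  (`normalize_start()`), excision of genes (`extract_feature()`, with
  origin wrap and strand handling) and of contiguous multi-gene arcs
  through the D-loop (`extract_segment()`), gap-fraction column
  masking and concatenation.
* **A tree engine**: pairwise-deletion p / JC69 distances, a
  deterministic Saitou–Nei neighbor-joining implementation, outgroup
  rooting, and column-resampling bootstrap supports. Trees are
  `ape::phylo`, so externally inferred trees can be swapped in.
* **Tree agreement**: patristic-distance correlation (Pearson +
  Spearman) and clade concordance — the fraction of the reference
  tree's non-trivial bipartitions shared by the comparison tree after
  pruning both to common tips.
* **The marker scan** (`run_scan()`): against a full-genome reference
  tree on all taxa, repeatedly subsample ~60% of the taxa, rebuild a
  tree per candidate marker, score concordance per replicate, and rank
  markers (`rank_segments()`, with one-sided Mann–Whitney U
  comparisons).
* **A mitogenome population simulator** (`simulate_mito_dataset()`)
  with known genealogy, vertebrate gene order, conserved coding genes
  and a 20× hypervariable D-loop, so the whole pipeline is testable
  offline with truth in hand.

## Worked example

```r
library(mitomarker)

# a 30-taxon synthetic population (plus outgroup), ~16.5 kb circular genome
bundle <- simulate_mito_dataset(sim_config(n_taxa = 30, seed = 7))
bundle$alignment
#> <annotated_alignment> 31 taxa x 16500 columns (circular)
#>   42 features: trnF, rnS, trnV, rnL, trnL2, nad1, trnI, trnQ

# heterogeneity concentrates in the control region
trk <- heterogeneity_track(bundle$alignment)
# mean H: dloop 0.504, cds 0.047

# the compact cob..rnS arc through the D-loop
seg <- extract_segment(bundle$alignment, segment_spec("cob", "rnS", via = "dloop"))
aln_ncol(seg)
#> [1] 3508

# the scan: 9 markers x 30 subsampling replicates at 60%
report <- run_scan(bundle$alignment, scan_config(
  n_replicates = 30, outgroup = "outgroup", seed = 5
))
glance(report)
#> # A tibble: 9 x 8
#>   segment    n_columns     n   min    q1 median    q3   max
#> 1 cob             1140    30 0.688 0.812  0.844 0.875 0.938
#> 2 cob-cox1        9266    30 0.938 1      1     1     1
#> 5 cob-rnS         3508    30 0.875 0.938  0.938 1     1
#> 9 full_mtdna     16500    30 0.938 1      1     1     1
#> ... (cob-nad1, cob-nad2, cob-rnL, cox1, dloop omitted here)

rk <- rank_segments(report, test = TRUE)
attr(rk, "pairwise") |> dplyr::filter(segment_a == "cob-rnS", segment_b == "cob")
#>   segment_a segment_b statistic       p_value
#> 1 cob-rnS   cob            842. 0.00000000128
```

Reading: each concordance is the fraction of the full-mtDNA reference
tree's clades recovered by that marker's tree in one 60% taxon
subsample (1 = every clade recovered). Here the full genome and long
composites sit at a median of 1.0, the 3.5 kb *cob–rnS* composite at
0.938, and the single gene *cob* at 0.844 — significantly below the
composite (one-sided Mann–Whitney p ≈ 1.3e−9). `autoplot(report)`
draws the box-and-whisker summary; `tidy(report)` returns the
per-replicate table.

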