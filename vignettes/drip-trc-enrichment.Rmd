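---
title: "Quantifying R-loop signal at transcription-replication conflicts with driptrc"
author: "driptrc maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying R-loop signal at transcription-replication conflicts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(driptrc)
```

## The analysis

R-loops — DNA:RNA hybrids left behind by transcription — become a genome
stability threat where the replisome meets RNA polymerase inside a
transcribed gene body. The geometry of that encounter matters: when a
replication fork fires from an origin inside a gene body, the fork moving
*against* transcription collides head-on (HO) with RNA polymerase, while the
fork moving *with* transcription is co-directional (CD). DRIP-seq (S9.6
immunoprecipitation followed by sequencing) maps R-loops genome-wide, so
comparing DRIP signal between a case sample and a control, separately in HO
and CD territory around intragenic replication origins, asks directly
whether a genotype accumulates collision-associated R-loops.

`driptrc` implements that comparison as a small pipeline:

1. **Binning** (`bin_reads`): aligned, duplicate-removed reads are counted
   into 100-nt bins by their strand-aware 5' end. Single-point assignment
   keeps the total count conserved exactly, which in turn makes the
   normalization arithmetic exact. (Overlap-based multi-bin counting is a
   near-equivalent alternative when reads and bins are both ~100 nt; the
   5'-end rule is the package's recorded choice.)
2. **Normalization** (`normalize_track`): every bin is scaled by
   `norm_target / library_size`, the classical reads-per-10M rescaling with
   a 10,000,000-read default target. The operation refuses to run twice.
3. **Oriented aggregation** (`aggregate_profile`): for each anchored region
   a 24-kb window (240 bins) centred on the bin-snapped anchor is read out
   in transcription orientation — for minus-strand gene bodies the bin order
   is inverted, so a negative offset always means "upstream of the origin in
   the transcription frame", which is where HO collisions live. Windows that
   would overrun a chromosome end are dropped, not padded, and counted;
   padding would bias edge-bin means.
4. **Sub-windows** (`split_sub_windows`): HO = oriented `[-6 kb, 0)`,
   CD = `[0, +6 kb)`, and their union, the 12-kb quantification window.
5. **Summaries** (`summarize_profile`, `window_average`, `ecdf_table`):
   per-bin mean (or lower-interpolation median) profiles with percentile
   bootstrap bands from resampling regions — the region, not the bin, is the
   independent unit — plus per-region window averages and their ECDF.
6. **Enrichment testing** (`build_table`, `compare_samples`): a 2x2 table
   per sample and window — rounded normalized in-window count vs the
   remainder of the normalized library, sample vs control — tested with the
   two-sided Fisher's exact test (minimum-likelihood rule, via
   `stats::fisher.test`) and Bonferroni-corrected over the batch. Summed
   counts enter the test directly; the bootstrap is used only for the
   profile bands.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `half_width` | 12,000 bp | metaprofile window half-width (24-kb window) |
| `bin_width` | 100 bp | bin size for counting and aggregation |
| `quant_half_width` | 6,000 bp | HO/CD sub-window width around the anchor |
| `norm_target` | 1e7 reads | common library scale after normalization |
| `n_boot` | 10,000 | bootstrap resamples for profile bands |
| `n_random_windows` | 50,000 | random negative-control windows (24 kb each) |

Anchors are snapped down to the containing 100-nt bin boundary so every
window tiles exactly 240 bins; the sub-kilobase phase of the grid is not
meaningful at the 100-nt bin scale. Bootstrap bands use the 2.5/97.5
percentiles; medians use lower interpolation for determinism at even counts.
Fifty thousand random 24-kb windows nominally span 1.2 Gb, about 38.8% of
the hg19 genome (3,095,677,412 bp over chr1-22, X, Y) — windows may overlap,
and the coverage figure deliberately ignores overlap.

## A statistical caveat the package enforces

The contingency table feeds *rounded normalized* counts to an exact count
test. Writing `s = norm_target / library_size`, an in-window normalized sum
is `s` times a raw count, so its variance is `s` times what the
hypergeometric model assumes. With deeply sequenced libraries
(`library_size >= norm_target`, `s <= 1`) the test is conservative; with
`s > 1` it is anti-conservative and can grossly overstate significance.
`build_table` and `compare_samples` therefore warn whenever the target
exceeds a library size. All synthetic analyses in this package set
`norm_target` equal to the simulated library size (`s = 1`), the regime the
10M target was designed for with typical real DRIP-seq libraries.

A second, subtler effect: rescaling every sample to a common total means
that strong enrichment in one compartment *dilutes* all others. If the HO
windows hold a fraction `q` of the library and the case sample is enriched
`f`-fold there, every other bin is deflated by `1 + q (f - 1)`. Whether the
resulting CD-window deficit reaches significance depends on `q` and the
in-window counts; with realistic genome-to-window ratios (`q` well under a
few percent, as for 727 windows in a 3-Gb genome) it does not. The synthetic
genome defaults (below) were sized to keep this artifact in the same
regime.

## What the generator simulates — and what it does not

`sim_config()` / `simulate_regions()` / `simulate_reads()` build a genome of
equal-length chromosomes, place non-overlapping gene bodies uniformly
(16–40 kb long, strands Bernoulli(1/2)), and anchor 727 origin-class regions
uniformly in the gene interior at least 6 kb from both ends plus 484
origin-free center-class regions anchored at the gene midpoint. The two
classes are disjoint gene sets here; the loader accepts tables where the
center regions are instead the same genes, so either reading of a real
region table works. Read counts are Poisson per 100-nt bin (rate
`background_rate`, default 2), multiplied by `fold_HO` (default 2) and
`fold_CD` (default 1) in the oriented sub-windows of origin-class regions in
the case sample only, then thinned or inflated to the configured library
size (5e5 reads by default) and materialized as 100-nt read intervals. An
optional gamma-mixed rate adds overdispersion; it is off by default so
expectations stay closed-form.

The default 4 x 80 Mb genome keeps the 727 HO windows at ~1.4% of the
library — sparse like the real genome, while fast to simulate. These
defaults are the package's standing desk-scale study conditions; the test
suite runs 200 null replicates on a smaller 60-region fixture and 20 seeds
at the full 727-region scale.

The generator does **not** emulate: mappability and blacklist structure, GC
bias, fragment-length variation, duplicate reads, peak-shaped (non-block)
enrichment profiles, biological replicate variability beyond Poisson, or
chromatin-driven background heterogeneity. Passing tests therefore show the
pipeline's arithmetic and inference behave correctly under the assumed
sampling model — not that any particular real dataset satisfies that model.

## Numerical and degenerate-input choices

- Coordinates are 0-based half-open throughout; an anchor equal to
  `gene_end` is rejected by the loader.
- Count rounding before Fisher is R's round-half-to-even, which is unbiased.
- A contingency table with a zero margin carries no information: p = 1,
  odds ratio undefined (`NA`).
- Odds ratios are the sample cross-product `(ad)/(bc)`, not the conditional
  MLE, so they match the intuitive in-window ratio.
- An all-zero pair of tracks yields a flagged degenerate table rather than
  an error; a single-region profile yields a degenerate bootstrap band with
  a warning.
- `normalize_track` on a zero-read library and aggregation over an empty
  region list are errors.
- Random-window sampling draws chromosomes proportionally to their count of
  positions where a full window fits, then positions uniformly, so the
  sampler is exactly uniform over valid placements.

## Known limitations

- The Bonferroni family is the invocation batch (samples x windows); the
  family behind any particular published adjusted p-value may differ, so
  adjusted values are comparable within a run, not across analyses.
- Summed-across-regions testing answers "is the window set enriched as a
  whole"; it does not identify which regions drive the signal.
- The bootstrap treats regions as independent; overlapping or clustered
  windows (possible in the random control) mildly understate band width.
- Mean bootstrap bands are computed by a resample-weight matrix product and
  are fast at 10,000 resamples; median bands fall back to an explicit loop
  and are noticeably slower at the same `n_boot`.

## End-to-end example

```{r example, eval = FALSE}
cfg <- sim_config(n_chroms = 2, chrom_length = 1e7,
                  n_origin_regions = 60, n_center_regions = 40,
                  fold_HO = 3,
                  library_size_control = 1e5, library_size_case = 1e5,
                  seed = 42)
fx <- export_fixture(cfg, "fixture", norm_target = 1e5)

rc <- run_config(n_boot = 1000, n_random_windows = 1000,
                 norm_target = 1e5, seed = 1)
run_profile(c(control = fx$control, case = fx$case),
            fx$regions, fx$chrom_sizes, "out_profile", rc)
res <- run_enrichment(c(control = fx$control, case = fx$case), "control",
                      fx$regions, fx$chrom_sizes, "out_test", rc)
res[, c("window", "odds_ratio", "p_adj")]
```

The head-on row comes back with an odds ratio near the injected fold and a
vanishing adjusted p, the co-directional row stays near 1 — the
orientation-restricted contrast the pipeline exists to measure.
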