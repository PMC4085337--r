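---
title: "Quantifying conservation and regulatory signal in first introns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying conservation and regulatory signal in first introns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(firstintron)
```

## The question and the method

First introns of multi-exon genes are, on average, the longest introns and
the most conserved, and in several lineages they are enriched for
transcriptional regulatory elements. `firstintron` implements a pipeline
for asking, on any combination of gene models, a per-base conservation
track, and regulatory peak sets, whether:

1. conservation decays with intron ordinal position (1st, 2nd, ... counted
   from the transcript 5' end);
2. regulatory-signal coverage of first introns rises with their
   conservation;
3. both trends scale with the gene's exon count and expression level;
4. within single genes, regulatory signal concentrates in the *conserved*
   sub-regions of the first intron; and
5. these patterns survive controls for promoter spillover, overlapping
   genes, and distance from the transcription start site (TSS).

The unit of measurement throughout is a *fraction of bases*: a base is
"conserved" when its track score (e.g. a PhastCons posterior) is at or
above a threshold (default 0.5, inclusive), and "covered" when it lies in
a peak. Bases missing from the track score 0, matching the semantics of
genome-browser conservation downloads where unaligned bases are absent.

## Intron preparation

Introns are the gaps between consecutive exons, with ordinals assigned in
transcript orientation (on the minus strand the intron with the greatest
genomic coordinates is ordinal 1). Before any overlay, `filter_introns()`
applies two rules and `trim_and_mask()` two more:

* a **1 kb length floor** (very short introns are dominated by splicing
  signal);
* an **outlier ceiling** at Q3 + 1.5 x IQR of the raw lengths of the
  post-floor cohort, pooled across all ordinals. Quartiles use the linear
  interpolation rule (`stats::quantile` type 7), recorded in
  `filter_config()` so the filter is bit-reproducible. The ceiling is
  inclusive and applied once; because the pooled length distribution keeps
  an upper tail of long first introns, a *second* application would
  recompute a lower fence and remove more — the filter is deliberately
  single-pass and therefore not idempotent in general;
* a **300 bp trim** at both intron ends, keeping splice-regulatory
  sequence out of the conservation estimates (trim x 2 must stay below the
  length floor);
* **repeat masking**: by default repeat bases are subtracted from the
  analysis regions (`repeat_mode = "mask"`); a strict mode drops any
  intron overlapping a repeat at all (`"drop"`). Both readings appear in
  the source material for this kind of filtering; neither is privileged,
  the default is the milder one.

Transcripts whose first intron fails these filters are excluded from
first-intron analyses, but their other introns still contribute to the
ordinal groups. When several transcripts per gene exist,
`select_representative()` offers a deterministic convention (most exons,
then longest span, then smallest id) — a declared guess, since no standard
rule exists.

Internally all coordinates are 1-based closed `GRanges`; BED-family inputs
(0-based half-open) and GTF (1-based closed) are converted at the IO
boundary. Keeping the native IRanges convention avoids re-deriving
interval arithmetic that GenomicRanges already guarantees.

## Statistics

**Ordinal comparison.** Per-ordinal conserved fractions are summarized by
medians/quartiles; group 1 is compared to each other group and to the
pooled rest with one-sided Wilcoxon rank-sum tests (exact enumeration for
<= 10 per side and no ties, tie-corrected normal approximation otherwise).

**Binned Kendall correlation.** Genes are sorted by the binning variable
and aggregated into consecutive bins of exactly `bin_size` genes (default
10 for conservation-vs-signal, 50 for expression); an incomplete trailing
bin is dropped rather than producing one bin with different variance.
Kendall tau-b (tie-corrected) is computed on the binned means *and* on the
raw pairs; the binned value is what a smoothing plot shows, the raw value
is the statistically calibrated one (at typical bin counts the null
standard deviation of the binned tau is ~0.07, an order of magnitude above
the pair-level statistic). Pairs with zero conservation *and* zero signal
are dropped by default (`drop_zero_zero`), since regions with neither
quantity carry no rank information and their retention only strengthens
observed positive trends.

**Exon-count regression.** Genes are grouped by exon count (G1 = 2 exons
... G20 = 21 exons, higher counts excluded), each group's *mean* value is
regressed on the exon count by ordinary least squares — so slopes are in
per-exon units, and R-squared measures how much of the between-group
variation the exon count explains.

**Gene-wise log-odds.** Each first intron's analysis bases are partitioned
into conserved (C) and non-conserved (N) parts, and each part into
signal-covered (S) and uncovered cells, giving base counts SC, NC, SN, NN
that always sum to the effective length. The enrichment statistic is

  log OR = ln[(SC x NN) / (NC x SN)],  SE = sqrt(1/SC + 1/NC + 1/SN + 1/NN)

with a Woolf-type 95% CI (log OR +/- 1.96 SE) and a Wald p-value; the
cohort tally counts genes significant at p < 0.01 in each direction. Cells
count *bases*, not peaks: the odds ratio is defined on the proportion of
signal in each part, and base counting is the only reading under which
that proportion and a 2x2 table coexist. Tables with one zero cell get the
Haldane-Anscombe 0.5 correction (flagged per gene); tables with two or
more zero cells (e.g. no conserved bases at all) are degenerate and the
gene is excluded from the tally.

## Controls

* `spillover_filter()` removes genes whose pooled promoter (2 kb upstream)
  + first-exon coverage is *at least as high* as the first-intron coverage
  (equality excludes, so a gene with zero signal everywhere is excluded).
  The pooled region, rather than the max of two separate fractions, is
  used because spillover is a property of the contiguous promoter-proximal
  region.
* `overlap_filter()` removes genes whose first intron intersects exons or
  2 kb flanks of a different gene.
* `tss_matched_compare()` compares first and second introns only within
  the 500-1000 bp TSS-distance window where the two distributions overlap,
  in five 100 bp bins (edges are a declared default; the window bounds are
  inclusive) plus an overall row, using one-sided (first > second)
  rank-sum tests; bins with fewer than 3 introns per side are reported but
  not tested. TSS distance is the unspliced genomic gap from the first
  exon's start to the intron's 5' boundary.
* `positional_bias()` asks where along the intron the signal peaks: each
  trimmed intron is cut into five equal bins (5' to 3' in transcript
  orientation), the argmax-density bin is recorded (ties resolved 5'-ward,
  all-zero introns skipped and counted), and introns shorter than the
  cohort median are excluded first so short introns cannot fake a 5' bias.

## The synthetic cohort generator

`simulate_cohort()` emits a complete input bundle — GTF gene models, a
bedGraph conservation track, a repeat-mask BED, one BED peak file per
mark, an expression TSV — in exactly the formats the pipeline reads, plus
a truth record for scoring recovery. It emulates:

* exon counts 2-25 (truncated negative binomial, mean ~8); first introns
  longest (log-normal, location ~7 kb vs 1.8-3.5 kb downstream); a 15%
  subpopulation with sub-kilobase first introns whose *second* introns
  fall inside the 500-1000 bp TSS window, so the TSS-matched control has
  members on both sides;
* conservation as discrete blocks (exponential lengths, mean 60 bp) rather
  than i.i.d. per-base scores — downstream interval logic (partitioning,
  merging, masking) is only exercised by blocky tracks — with per-ordinal
  target fractions defaulting to 0.08 / 0.05 / 0.03 / 0.02 (ordinal 4+),
  plus sub-threshold "noise" blocks that must be rejected by the 0.5 cut;
* an exon-count coupling on ordinal-1 conservation only,
  c1 x (1 + 0.08 (n_exons - mean)). The 0.08 default is a power choice:
  it gives the ordinal-1 group-mean regression R-squared ~0.9, decisively
  above the noise floor of an uncoupled ordinal (R-squared over ~18 noisy
  group means can drift to ~0.3 by chance);
* expression for four pseudo-tissues coupled to the *realized* first-intron
  conservation through a Gaussian copula with planted Kendall tau
  (default 0.3);
* per-mark peaks: inside first-intron trimmed spans, coverage is realized
  base-by-base with two rates — p1 on conserved bases, p0 elsewhere, with
  logit(p1) - logit(p0) equal to the planted log-odds — so the planted
  effect is exact *and* base counts are independent draws, which is what
  keeps the gene-wise Wald test calibrated (~1% of null genes at p < 0.01).
  Everywhere else (flanks, exons, downstream introns) peaks are placed as
  blocks with mark-typical widths: narrow for DHS/TFBS/H3K4me3, broad for
  H3K4me1/H3K9me3. Active marks carry positive planted log-odds, the
  repressive H3K9me3 and the insulator CTCF are flat;
* optional adversarial fixtures: nested genes planted inside host first
  introns (for the overlap filter) and `spike_spillover()`, which blankets
  chosen genes' promoters and first exons with signal spilling into the
  intron (for the spillover filter).

`null = TRUE` zeroes every planted effect. A seed is mandatory and the
bundle is byte-reproducible given it.

### What the generator does *not* emulate

No nucleotide sequence (the analysis never reads one), no realistic
chromosome sizes or GC structure, no alternative splicing (one transcript
per gene), no correlated placement of different marks, and no biological
relationship between repeats and conservation (the mask is independent).
Passing recovery tests therefore demonstrates that the *pipeline* measures
what was planted under its own model assumptions — not that those
assumptions hold in real genomes.

## Numerical conventions and edge cases

* Fractions over zero bases are `NA` sentinels, never 0/0 = 0; genes whose
  trimmed first intron is fully masked are excluded and logged.
* The conservation threshold comparison is inclusive (score >= 0.5) with
  no rounding of track scores.
* Replicate peak files of one mark are merged by union; peak sets are
  always reduced to disjoint intervals.
* All-tied rank-sum comparisons return p = 1 (one-sided).
* Correlations need two bins and non-constant margins, regressions two
  non-empty groups; anything less returns `NA` sentinels rather than
  fabricated zeros.
* Problem sizes used by the validation suite: a 2000-gene planted cohort,
  a 1000-gene null cohort, a 6000-gene single-mark cohort for the
  positional-bias scan, and a 400-gene spiked cohort — sizes at which
  every recovery tolerance has comfortable Monte-Carlo margin.

## Limitations

The Wald test on base counts assumes per-base independence; on real peak
data, where coverage is blocky, its per-gene p-values are optimistic and
the cohort tally should be read as descriptive (the CI half-widths make
the clustering visible). The outlier fence is cohort-relative, so adding
or removing transcripts changes which introns survive. The TSS-distance
window and bin edges, the representative-transcript rule, and the
zero-zero exclusion are declared conventions, configurable where the
underlying choice is genuinely open.
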