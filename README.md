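# firstintron

Conservation and regulatory-signal enrichment analysis for first introns.

First introns are typically the longest and most conserved introns of
multi-exon genes, and a natural place to look for transcriptional
regulatory elements under purifying selection. `firstintron` turns that
question into a reusable, tested pipeline: given gene models, a per-base
conservation score track and regulatory peak sets (open chromatin, TF
binding, histone marks), it measures

- per-ordinal conservation: the fraction of intron bases with score >= 0.5,
  for introns grouped by ordinal position (1st, 2nd, ... from the
  transcript 5' end), with Wilcoxon rank-sum comparisons of the first
  group against the rest;
- binned Kendall correlations between first-intron conservation and
  signal coverage, and between expression (log2(RPKM+1)) and conservation;
- exon-count-group regressions (G1 = 2-exon genes ... G20 = 21-exon
  genes; group mean vs exon count by OLS);
- a gene-wise log-odds enrichment of signal in conserved vs non-conserved
  first-intron bases,

  log OR = ln[(SC·NN)/(NC·SN)],  CI = log OR ± z·sqrt(1/SC + 1/NC + 1/SN + 1/NN),

  where SC/NC/SN/NN are base counts in the 2×2
  conserved-by-signal-covered table, with a Woolf-type 95% CI, Wald
  p-values and a p < 0.01 cohort tally;
- confounder controls: promoter-spillover exclusion, overlapping-gene
  exclusion, TSS-distance-matched first-vs-second comparison, and a
  five-bin positional-bias scan.

Introns are prepared with the standard filtering chain: 1 kb length
floor, pooled Q3 + 1.5·IQR outlier ceiling, 300 bp splice-proximal trims,
and repeat masking (subtract bases, or optionally drop introns).

A synthetic-genome generator (`simulate_cohort()`) emits complete input
bundles — GTF, bedGraph, BED peak/mask files, expression TSV — with
planted ordinal conservation decay, per-mark log-odds couplings, exon-count
and expression couplings, and adversarial fixtures (nested genes, promoter
spillover), so the whole pipeline is validated end-to-end by parameter
recovery. See `vignettes/first-intron-analysis.Rmd` for the methods.

## Worked example

```r
library(firstintron)

# a synthetic bundle with planted effects (any real GTF/bedGraph/BED/TSV
# bundle in the same layout works identically)
dir <- tempfile()
simulate_bundle(sim_config(n_genes = 120, seed = 7), dir)

res <- run_pipeline(run_config(bundle_dir = dir))

res$ordinal_table[1:3, ]
#>   ordinal   n         q1     median         q3
#> 1       1  46 0.05767616 0.07874508 0.10337760
#> 2       2 104 0.01283856 0.04592532 0.08078424
#> 3       3 104 0.00000000 0.01954668 0.04959977

res$first_vs_rest[1, ]
#>   comparison n1  n2    median1      median2      p_value
#> 1     pooled 46 599 0.07874508 0.0004764173 2.516923e-16

res$odds_tally[res$odds_tally$mark == "DHS", ]
#>   mark n_total n_sig_positive n_sig_negative
#> 2  DHS      45             43              0
```

Reading: first introns hold a median ~7.9% conserved bases against ~0.05%
across all other introns pooled (rank-sum p ≈ 3e-16), and in 43 of 45
genes the DNase-hypersensitivity signal is significantly enriched in the
conserved part of the first intron — recovering the planted structure.
Per-table TSV reports (with provenance headers) are written when
`run_config(outdir = ...)` is set.

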