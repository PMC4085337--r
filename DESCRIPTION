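Package: firstintron
Title: Conservation and Regulatory-Signal Enrichment in First Introns
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An analysis pipeline for quantifying evolutionary conservation
    and regulatory-chromatin signal in introns grouped by ordinal position,
    with emphasis on the first intron. Derives introns from gene models,
    applies length/outlier filters, splice-proximal trimming and repeat
    masking, overlays per-base conservation score tracks and peak sets,
    and computes conserved-site and signal-coverage proportions, binned
    Kendall rank correlations, exon-count-group regressions, a gene-wise
    conserved-versus-nonconserved log-odds enrichment statistic with
    Woolf-type confidence intervals, and confounder-control procedures
    (promoter spillover and gene-overlap exclusion, TSS-distance-matched
    comparison, positional-bias scan). Includes a synthetic-genome
    generator with planted effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
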