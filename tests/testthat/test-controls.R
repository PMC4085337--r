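# Confounder-control procedures.

test_that("spillover_filter keeps genes only when the intron signal wins", {
  sf <- spillover_filter(c("a", "b", "c", "d"),
                         intron_fraction = c(0.3, 0.2, 0.0, NA),
                         promoter_fraction = c(0.1, 0.2, 0.0, 0.1))
  expect_equal(sf$kept, "a")
  expect_equal(sf$log$reason[sf$log$gene_id == "b"],
               "promoter_at_least_as_high")      # equality excludes
  expect_false(sf$log$kept[sf$log$gene_id == "c"])  # 0 >= 0 excludes
  expect_equal(sf$log$reason[sf$log$gene_id == "d"], "missing")
})

test_that("overlap_filter removes first introns touching foreign features", {
  mk <- function(s0, e0, strand, id, gene) {
    transcript_model(id, gene, "chr1", strand, s0 + 1, e0)
  }
  # isolated gene with a 10 kb first intron
  iso <- mk(c(50000, 61000), c(50500, 61400), "+", "iso.1", "iso")
  # host gene whose first intron contains a nested gene's exon
  host <- mk(c(100000, 111000), c(100500, 111400), "+", "host.1", "host")
  nested <- mk(c(105000, 105600), c(105200, 105800), "+", "nest.1", "nest")
  # gene whose first intron ends 1999 bases from a neighbour's first exon
  near <- mk(c(200000, 206000), c(200500, 206400), "+", "near.1", "near")
  neigh <- mk(c(207900, 209500), c(208300, 209900), "+", "neigh.1", "neigh")

  all_t <- list(iso, host, nested, near, neigh)
  introns <- extract_introns(all_t)
  fi <- introns[introns$ordinal == 1L &
                  introns$gene_id %in% c("iso", "host", "near"), ]
  ov <- overlap_filter(fi, all_t, flank = 2000)
  expect_true("iso" %in% ov$kept)
  expect_false("host" %in% ov$kept)
  expect_false("near" %in% ov$kept)  # 1999 < 2000 bp flank
})

test_that("overlap and spillover filters are idempotent", {
  res <- pipeline_result("small", small_cohort())
  sp <- res$spillover[res$spillover$mark == "DHS", ]
  again <- spillover_filter(sp$gene_id, sp$intron_fraction,
                            sp$promoter_fraction)
  expect_setequal(again$kept, sp$gene_id[sp$kept])
})

test_that("tss_matched_compare bins inclusively and tests first > second", {
  set.seed(401)
  first <- data.frame(distance = c(500, runif(60, 500, 1000)),
                      value = c(0.5, runif(60)))
  second <- data.frame(distance = runif(60, 500, 1000),
                       value = runif(60))
  res <- tss_matched_compare(first, second)
  expect_equal(res$bin[nrow(res)], "overall")
  expect_equal(sum(res$n_first[res$bin != "overall"]), nrow(first))
  # identical distributions: one-sided p near 1/2
  ov <- res[res$bin == "overall", ]
  expect_gt(ov$p_value, 0.05)

  # boundary: a lone intron at exactly distance 500 enters bin 1
  solo <- tss_matched_compare(data.frame(distance = 500, value = 1),
                              data.frame(distance = 999, value = 0))
  expect_equal(solo$n_first[1], 1L)
  expect_false(solo$tested[1])  # below min_n, flagged not tested

  shifted <- tss_matched_compare(
    data.frame(distance = runif(100, 500, 1000), value = runif(100) + 0.6),
    data.frame(distance = runif(100, 500, 1000), value = runif(100)))
  expect_lt(shifted[shifted$bin == "overall", "p_value"], 0.01)
})

test_that("positional_bias finds planted 5' signal and breaks ties 5'-ward", {
  introns <- data.frame(chrom = "chr1", start = 1L, end = 5000L,
                        strand = "+", raw_length = 5000L)
  # trimmed span is [301, 4700]; signal only in its first fifth
  five_prime <- positional_bias(introns, gr0(300, 1180), trim = 300,
                                min_raw_length = 0)
  expect_equal(five_prime$fraction_per_bin, c(1, 0, 0, 0, 0))

  uniform <- positional_bias(introns, gr0(0, 6000), trim = 300,
                             min_raw_length = 0)
  expect_equal(uniform$fraction_per_bin[1], 1)  # all-equal ties -> bin 1

  minus <- data.frame(chrom = "chr1", start = 1L, end = 5000L,
                      strand = "-", raw_length = 5000L)
  # genomically 3'-most fifth is the transcript 5' end on the minus strand
  m <- positional_bias(minus, gr0(3820, 4700), trim = 300,
                       min_raw_length = 0)
  expect_equal(m$fraction_per_bin, c(1, 0, 0, 0, 0))

  silent <- positional_bias(introns, GenomicRanges::GRanges(), trim = 300,
                            min_raw_length = 0)
  expect_equal(silent$n_skipped, 1L)
  expect_equal(silent$n_introns, 0L)
})

test_that("positional_bias fractions sum to one and respect the length floor", {
  set.seed(402)
  n <- 40
  lens <- sample(3000:9000, n)
  introns <- data.frame(chrom = "chr1",
                        start = cumsum(c(1, lens[-n] + 500)),
                        strand = "+", raw_length = lens)
  introns$end <- introns$start + lens - 1L
  starts <- sort(sample(seq(0, 290000, 50), 60))
  peaks <- gr0(starts, starts + 40)
  pb <- positional_bias(introns, peaks, trim = 300)
  expect_equal(sum(pb$fraction_per_bin), 1)
  expect_equal(pb$n_short, sum(lens < median(lens)))
})
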