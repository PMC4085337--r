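# Intron derivation, filtering, trimming/masking, flanks, TSS distances.
# Fixture coordinates are written 0-based half-open and converted by the
# helpers, so they can be read straight off interval sketches.

tm0 <- function(exon_s0, exon_e0, strand = "+", id = "t1", gene = "g1") {
  transcript_model(id, gene, "chr1", strand, exon_s0 + 1, exon_e0)
}

test_that("extract_introns returns exon gaps with transcript-oriented ordinals", {
  expect_equal(nrow(extract_introns(tm0(0, 100))), 0L)

  plus <- extract_introns(tm0(c(0, 200, 450), c(100, 300, 600)))
  expect_equal(plus$start, c(101L, 301L))
  expect_equal(plus$end, c(200L, 450L))
  expect_equal(plus$ordinal, c(1L, 2L))
  expect_equal(plus$raw_length, c(100L, 150L))

  minus <- extract_introns(tm0(c(0, 200), c(100, 300), strand = "-"))
  expect_equal(minus$start, 101L)
  expect_equal(minus$ordinal, 1L)

  minus3 <- extract_introns(tm0(c(0, 200, 450), c(100, 300, 600), strand = "-"))
  expect_equal(minus3$ordinal, c(2L, 1L))  # rightmost gap is the first intron
})

test_that("introns and exons tile the transcript span without gaps", {
  set.seed(41)
  for (rep in 1:20) {
    k <- sample(2:8, 1)
    cuts <- sort(sample(seq(10, 5000, by = 10), 2 * k))
    t <- tm0(cuts[seq(1, 2 * k, 2)], cuts[seq(2, 2 * k, 2)],
             strand = sample(c("+", "-"), 1))
    introns <- extract_introns(t)
    pieces <- c(GenomicRanges::GRanges("chr1",
                                       IRanges::IRanges(t$exon_start, t$exon_end)),
                GenomicRanges::GRanges(introns$chrom,
                                       IRanges::IRanges(introns$start, introns$end)))
    merged <- GenomicRanges::reduce(pieces)
    expect_equal(length(merged), 1L)
    expect_equal(sum(GenomicRanges::width(pieces)),
                 GenomicRanges::width(merged))
  }
})

test_that("strand reversal mirrors intron coordinates and reverses ordinals", {
  set.seed(42)
  for (rep in 1:20) {
    k <- sample(2:7, 1)
    cuts <- sort(sample(seq(10, 4000, by = 10), 2 * k))
    es <- cuts[seq(1, 2 * k, 2)]; ee <- cuts[seq(2, 2 * k, 2)]
    span_max <- max(ee) + 1
    fwd <- extract_introns(tm0(es, ee, strand = "+"))
    # reflect coordinates around span_max: [s, e) -> [max - e, max - s)
    rev_t <- tm0(sort(span_max - ee - 1), sort(span_max - es - 1),
                 strand = "-")
    rev <- extract_introns(rev_t)
    expect_equal(sort(rev$raw_length), sort(fwd$raw_length))
    # the genomically reflected first intron keeps ordinal 1
    expect_equal(rev$raw_length[rev$ordinal == 1],
                 fwd$raw_length[fwd$ordinal == 1])
  }
})

test_that("filter_introns applies the 1 kb floor then the pooled IQR ceiling", {
  mk <- function(lens) {
    data.frame(transcript_id = "t", gene_id = "g", chrom = "chr1",
               strand = "+", start = 1L, end = lens, ordinal = seq_along(lens),
               raw_length = as.integer(lens))
  }
  expect_equal(nrow(filter_introns(mk(c(500, 900)))), 0L)

  # post-floor lengths: Q3 (type 7) = 2500, IQR = 1000, ceiling = 4000
  got <- filter_introns(mk(c(1200, 1500, 2000, 2500, 100000)))
  expect_equal(got$raw_length, c(1200L, 1500L, 2000L, 2500L))

  # all equal: IQR 0, ceiling = Q3 itself, boundary inclusive
  expect_equal(nrow(filter_introns(mk(rep(2000, 5)))), 5L)
})

test_that("filter_introns removes exactly the introns outside the fences", {
  introns <- extract_introns(small_cohort()$sim$transcripts)
  once <- filter_introns(introns)
  post_floor <- introns$raw_length[introns$raw_length >= 1000]
  fence <- unname(stats::quantile(post_floor, 0.75, type = 7) +
                    1.5 * diff(stats::quantile(post_floor, c(0.25, 0.75),
                                               type = 7)))
  keep <- introns$raw_length >= 1000 & introns$raw_length <= fence
  expect_equal(once$raw_length, introns$raw_length[keep])
  # order preserved
  expect_equal(once$transcript_id, introns$transcript_id[keep])
})

test_that("trim_and_mask trims 300 bp per end and subtracts mask bases", {
  df <- data.frame(transcript_id = "t1", gene_id = "g1", chrom = "chr1",
                   strand = "+", start = 1L, end = 1000L, ordinal = 1L,
                   raw_length = 1000L)

  plain <- trim_and_mask(df, cfg = filter_config())
  expect_equal(plain$introns$effective_length, 400L)
  expect_equal(GenomicRanges::start(plain$regions), 301L)
  expect_equal(GenomicRanges::end(plain$regions), 700L)

  masked <- trim_and_mask(df, gr0(400, 500), filter_config())
  expect_equal(masked$introns$effective_length, 300L)
  expect_equal(GenomicRanges::start(masked$regions), c(301L, 501L))
  expect_equal(GenomicRanges::end(masked$regions), c(400L, 700L))

  gone <- trim_and_mask(df, gr0(0, 1000), filter_config())
  expect_equal(gone$introns$effective_length, 0L)
  expect_true(gone$introns$excluded)

  dropped <- trim_and_mask(df, gr0(400, 500),
                           filter_config(repeat_mode = "drop"))
  expect_true(dropped$introns$excluded)
  expect_equal(length(dropped$regions), 0L)
})

test_that("masking matches per-base subtraction on random instances", {
  set.seed(11)
  for (rep in 1:25) {
    len <- sample(800:3000, 1)
    df <- data.frame(transcript_id = "t", gene_id = "g", chrom = "chr1",
                     strand = "+", start = 1L, end = len, ordinal = 1L,
                     raw_length = as.integer(len))
    nm <- sample(0:4, 1)
    mask <- if (nm > 0) {
      ms <- sort(sample(0:len, 2 * nm))
      gr0(ms[seq(1, 2 * nm, 2)], ms[seq(2, 2 * nm, 2)])
    } else GenomicRanges::GRanges()
    got <- trim_and_mask(df, mask, filter_config())
    trimmed <- seq.int(1 + 300, len - 300)
    expected <- setdiff(trimmed, bases_of(mask))
    expect_equal(got$introns$effective_length, length(expected))
    expect_equal(bases_of(got$regions), expected)
  }
})

test_that("flank_regions are strand-aware and clipped at the chromosome start", {
  up <- flank_regions(tm0(c(5000, 7000), c(5500, 7400)))["upstream"]
  expect_equal(GenomicRanges::start(up), 3001L)
  expect_equal(GenomicRanges::end(up), 5000L)

  clipped <- flank_regions(tm0(c(800, 2000), c(1000, 2400)))["upstream"]
  expect_equal(GenomicRanges::start(clipped), 1L)
  expect_equal(GenomicRanges::end(clipped), 800L)

  dn <- flank_regions(tm0(c(5000, 7000), c(5500, 7400),
                          strand = "-"))["downstream"]
  expect_equal(GenomicRanges::start(dn), 3001L)
  expect_equal(GenomicRanges::end(dn), 5000L)
})

test_that("tss_distance is the genomic gap from the TSS to the intron 5' end", {
  t_plus <- tm0(c(0, 200, 450), c(100, 300, 600))
  introns <- extract_introns(t_plus)
  d <- tss_distance(introns, list(t_plus))
  expect_equal(d[introns$ordinal == 1], 100L)
  expect_equal(d[introns$ordinal == 2], 300L)

  t_minus <- tm0(c(0, 200), c(100, 300), strand = "-")
  im <- extract_introns(t_minus)
  expect_equal(tss_distance(im, list(t_minus)), 100L)
})

test_that("select_representative prefers exons, then span, then id", {
  a <- tm0(c(0, 200, 400, 600, 800), c(100, 300, 500, 700, 900), id = "a")
  b <- tm0(c(0, 200, 400), c(100, 300, 2000), id = "b")
  expect_identical(select_representative(list(b, a))$transcript_id, "a")
  expect_identical(select_representative(list(a))$transcript_id, "a")

  wide <- tm0(c(0, 200, 400), c(100, 300, 3000), id = "w")
  expect_identical(select_representative(list(b, wide))$transcript_id, "w")

  b2 <- tm0(c(0, 200, 400), c(100, 300, 2000), id = "a0")
  expect_identical(select_representative(list(b, b2))$transcript_id, "a0")
})

test_that("GTF and BED12 gene-model readers agree with in-memory models", {
  t1 <- tm0(c(0, 200, 450), c(100, 300, 600), id = "tx1", gene = "gA")
  t2 <- tm0(c(1000, 1400), c(1200, 1600), strand = "-", id = "tx2",
            gene = "gB")
  gtf <- tempfile(fileext = ".gtf")
  firstintron:::write_gtf(list(t1, t2), gtf)
  models <- read_gene_models(gtf)
  expect_setequal(names(models), c("tx1", "tx2"))
  expect_equal(models$tx1$exon_start, t1$exon_start)
  expect_equal(models$tx2$exon_end, t2$exon_end)
  expect_equal(models$tx2$strand, "-")

  bed12 <- tempfile(fileext = ".bed")
  writeLines(paste(c("chr1", 0, 600, "tx1", 0, "+", 0, 600, "0", 3,
                     "100,100,150", "0,200,450"), collapse = "\t"), bed12)
  m <- read_bed12_models(bed12)
  expect_equal(m$tx1$exon_start, t1$exon_start)
  expect_equal(m$tx1$exon_end, t1$exon_end)
})
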