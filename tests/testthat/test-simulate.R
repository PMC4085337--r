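# Synthetic-cohort generator: determinism, round-trips, planted structure.

test_that("identical seeds give identical cohorts and byte-identical bundles", {
  cfg <- sim_config(n_genes = 40, seed = 555)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_equal(a$truth, b$truth)
  expect_true(identical(a$track, b$track))
  expect_true(identical(a$peaks, b$peaks))
  expect_true(identical(a$expression, b$expression))

  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  write_bundle(a, d1); write_bundle(b, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  }
  expect_false(identical(simulate_cohort(sim_config(n_genes = 40,
                                                    seed = 556))$track,
                         a$track))
})

test_that("bundles round-trip losslessly through the package readers", {
  fx <- small_cohort()
  sim <- fx$sim
  back <- read_bundle(fx$dir)
  expect_setequal(names(back$transcripts), names(sim$transcripts))
  for (id in names(sim$transcripts)) {
    expect_equal(back$transcripts[[id]]$exon_start,
                 sim$transcripts[[id]]$exon_start)
    expect_equal(back$transcripts[[id]]$strand, sim$transcripts[[id]]$strand)
  }
  expect_equal(GenomicRanges::start(back$track),
               GenomicRanges::start(sim$track))
  expect_equal(S4Vectors::mcols(back$track)$score,
               S4Vectors::mcols(sim$track)$score)
  for (m in names(sim$peaks)) {
    expect_equal(GenomicRanges::ranges(back$peaks[[m]]),
                 GenomicRanges::ranges(sim$peaks[[m]]), label = m)
  }
  expect_equal(GenomicRanges::ranges(back$mask),
               GenomicRanges::ranges(sim$mask))
  expect_equal(back$expression, sim$expression)
  expect_equal(back$truth$planted$tau_expr, sim$truth$planted$tau_expr)
})

test_that("generated structure satisfies the transcript-model contracts", {
  sim <- small_cohort()$sim
  introns <- extract_introns(sim$transcripts)
  expect_true(all(introns$raw_length >= 1))
  # track steps are non-overlapping
  expect_false(any(GenomicRanges::countOverlaps(sim$track, sim$track) > 1))
  expect_true(all(S4Vectors::mcols(sim$track)$score >= 0 &
                    S4Vectors::mcols(sim$track)$score <= 1))
  # peaks merged: no internal overlap
  for (m in names(sim$peaks)) {
    expect_false(any(GenomicRanges::countOverlaps(sim$peaks[[m]],
                                                  sim$peaks[[m]]) > 1))
  }
  # planted overlap genes really sit inside host first introns
  ovl <- grep("^GOVL", names(sim$transcripts), value = TRUE)
  expect_equal(length(ovl), 3L)
  fi <- introns[introns$ordinal == 1L & !grepl("^GOVL", introns$gene_id), ]
  fi_gr <- GenomicRanges::GRanges(fi$chrom, IRanges::IRanges(fi$start, fi$end))
  for (id in ovl) {
    t <- sim$transcripts[[id]]
    ex <- GenomicRanges::GRanges(t$chrom,
                                 IRanges::IRanges(t$exon_start, t$exon_end))
    expect_true(all(IRanges::overlapsAny(ex, fi_gr, ignore.strand = TRUE)))
  }
})

test_that("a null configuration plants no effects", {
  cfg <- sim_config(n_genes = 30, seed = 900, null = TRUE)
  sim <- simulate_cohort(cfg)
  expect_true(sim$truth$planted$null)
  expect_equal(unname(sim$truth$planted$mark_log_odds), rep(0, 6))
  expect_equal(sim$truth$planted$tau_expr, 0)
  expect_equal(sim$truth$planted$exon_coupling, 0)
  expect_equal(length(unique(sim$truth$planted$cons_levels)), 1L)
})

test_that("infeasible length configurations are rejected", {
  expect_error(sim_config(n_genes = 10, seed = 1,
                          intron_meanlog = c(first = log(500),
                                             second = log(500),
                                             third = log(500),
                                             rest = log(500))),
               "infeasible")
  expect_error(sim_config(n_genes = 10), "seed")
})

test_that("spiking spillover genes covers their promoters", {
  sim <- small_cohort()$sim
  introns <- extract_introns(sim$transcripts)
  fi <- introns[introns$ordinal == 1L & introns$raw_length > 2000 &
                  !grepl("^GOVL", introns$gene_id), ]
  pick <- fi$gene_id[1:4]

  unspiked <- spike_spillover(sim, character(0))
  expect_identical(unspiked$peaks, sim$peaks)

  spiked <- spike_spillover(sim, pick, marks = "DHS")
  expect_equal(spiked$truth$spiked, sort(pick))
  for (g in pick) {
    t <- sim$transcripts[[paste0(g, ".1")]]
    fr <- flank_regions(t, filter_config())
    up <- fr[names(fr) == "upstream"]
    expect_equal(coverage_fraction(up, spiked$peaks$DHS), 1)
  }
})

test_that("realized conserved fractions track the per-ordinal targets", {
  sim <- planted_cohort()$sim
  means <- unlist(sim$truth$realized$mean_c_by_ordinal)
  targets <- c(mean(sim$truth$genes$target_c1), 0.05, 0.03, 0.02)
  for (k in 1:4) {
    expect_lt(abs(unname(means[as.character(k)]) - targets[k]), 0.01)
  }
})
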