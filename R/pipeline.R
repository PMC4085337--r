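## End-to-end orchestration: annotation -> coverage -> group statistics ->
## gene-wise odds -> controls, with per-stage gene/intron counts and
## deterministic TSV report tables.

#' Pipeline run configuration
#'
#' @param bundle_dir Directory in [write_bundle()] layout; individual
#'   paths below override its defaults.
#' @param gtf,conservation,mask,peaks,expression Input paths (`peaks` is a
#'   named vector/list, one path per mark).
#' @param filter A [filter_config()].
#' @param bin_size_cons Genes per bin for the conservation-vs-signal
#'   correlations; default 10.
#' @param bin_size_expr Genes per bin for the expression correlation;
#'   default 50.
#' @param alpha CI level complement for the gene-wise odds; default 0.05.
#' @param sig_p Gene-wise significance threshold; default 0.01.
#' @param representative Collapse to one representative transcript per
#'   gene before analysis.
#' @param drop_zero_zero Drop double-zero pairs before correlations.
#' @param max_ordinal Highest ordinal group reported; default 20.
#' @param max_regression_ordinal Exon-count regressions are fitted for
#'   ordinals 1..this; default 3.
#' @param outdir Optional directory for the TSV report bundle.
#' @return A `run_config` list.
#' @export
run_config <- function(bundle_dir = NULL, gtf = NULL, conservation = NULL,
                       mask = NULL, peaks = NULL, expression = NULL,
                       filter = filter_config(), bin_size_cons = 10L,
                       bin_size_expr = 50L, alpha = 0.05, sig_p = 0.01,
                       representative = FALSE, drop_zero_zero = TRUE,
                       max_ordinal = 20L, max_regression_ordinal = 3L,
                       outdir = NULL) {
  if (!is.null(bundle_dir)) {
    if (is.null(gtf)) gtf <- file.path(bundle_dir, "genes.gtf")
    if (is.null(conservation))
      conservation <- file.path(bundle_dir, "conservation.bedGraph")
    if (is.null(mask)) mask <- file.path(bundle_dir, "mask.bed")
    if (is.null(peaks)) {
      pf <- list.files(bundle_dir, pattern = "^peaks_.*\\.bed$",
                       full.names = TRUE)
      peaks <- stats::setNames(pf, sub("^peaks_(.*)\\.bed$", "\\1",
                                       basename(pf)))
    }
    if (is.null(expression)) {
      ep <- file.path(bundle_dir, "expression.tsv")
      if (file.exists(ep)) expression <- ep
    }
  }
  for (p in c(gtf, conservation, mask, unlist(peaks), expression)) {
    if (!is.null(p) && !file.exists(p)) stop("input file not found: ", p)
  }
  structure(list(gtf = gtf, conservation = conservation, mask = mask,
                 peaks = peaks, expression = expression, filter = filter,
                 bin_size_cons = as.integer(bin_size_cons),
                 bin_size_expr = as.integer(bin_size_expr),
                 alpha = alpha, sig_p = sig_p,
                 representative = representative,
                 drop_zero_zero = drop_zero_zero,
                 max_ordinal = as.integer(max_ordinal),
                 max_regression_ordinal = as.integer(max_regression_ordinal),
                 outdir = outdir),
            class = "run_config")
}

config_provenance <- function(cfg) {
  f <- cfg$filter
  sprintf(paste0("# firstintron %s | min_intron_length=%d trim=%d outlier_k=%g ",
                 "cons_threshold=%g flank=%d repeat_mode=%s bin_cons=%d ",
                 "bin_expr=%d alpha=%g sig_p=%g representative=%s ",
                 "drop_zero_zero=%s"),
          as.character(utils::packageVersion("firstintron")),
          f$min_intron_length, f$trim, f$outlier_k,
          f$conservation_threshold, f$flank_length, f$repeat_mode,
          cfg$bin_size_cons, cfg$bin_size_expr, cfg$alpha, cfg$sig_p,
          cfg$representative, cfg$drop_zero_zero)
}

write_report_tsv <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes annotation, coverage, group statistics, gene-wise odds and the
#' control procedures in order, logging gene/intron counts at every filter
#' step. With `cfg$outdir` set, every table is also written as TSV with a
#' provenance header; identical configs yield byte-identical files.
#'
#' @param cfg A [run_config()].
#' @return A list of result tables: `counts`, `introns`, `summaries`
#'   (per-intron fractions), `ordinal_table`, `first_vs_rest`,
#'   `correlations` (per mark, binned + raw tau), `exon_regression`,
#'   `expression_correlation`, `odds` (per gene x mark), `odds_tally`,
#'   `spillover`, `overlap`, `tss_matched`, `positional_bias`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  fcfg <- cfg$filter
  thr <- fcfg$conservation_threshold
  counts <- list()
  log_count <- function(step, genes, introns) {
    counts[[length(counts) + 1L]] <<- data.frame(step = step,
                                                 n_genes = genes,
                                                 n_introns = introns)
  }

  ## inputs ---------------------------------------------------------------
  transcripts <- read_gene_models(cfg$gtf)
  track <- read_score_track(cfg$conservation)
  mask <- if (is.null(cfg$mask)) GenomicRanges::GRanges() else
    read_mask(cfg$mask)
  peaks <- lapply(cfg$peaks, read_peaks)
  names(peaks) <- names(cfg$peaks)
  expr_tab <- if (is.null(cfg$expression)) NULL else
    read_expression(cfg$expression)

  if (cfg$representative) {
    by_gene <- split(transcripts,
                     vapply(transcripts, function(t) t$gene_id, character(1)))
    transcripts <- lapply(by_gene, select_representative)
    names(transcripts) <- vapply(transcripts,
                                 function(t) t$transcript_id, character(1))
  }

  ## annotation -----------------------------------------------------------
  introns0 <- extract_introns(transcripts)
  log_count("extracted", length(unique(introns0$gene_id)), nrow(introns0))
  introns1 <- filter_introns(introns0, fcfg)
  log_count("length_filtered", length(unique(introns1$gene_id)),
            nrow(introns1))
  tm <- trim_and_mask(introns1, mask, fcfg)
  introns <- tm$introns[!tm$introns$excluded, , drop = FALSE]
  regions <- tm$regions[S4Vectors::mcols(tm$regions)$intron_id %in%
                          introns$intron_id]
  log_count("trimmed_masked", length(unique(introns$gene_id)), nrow(introns))

  ## coverage -------------------------------------------------------------
  summ <- region_summaries(regions, track = track, peaks = peaks,
                           threshold = thr, id_col = "intron_id")
  summ <- merge(introns[, c("intron_id", "transcript_id", "gene_id",
                            "ordinal", "raw_length")],
                summ, by.x = "intron_id", by.y = "region_id", sort = FALSE)
  summ <- summ[order(summ$gene_id, summ$ordinal), , drop = FALSE]
  rownames(summ) <- NULL

  ## ordinal groups -------------------------------------------------------
  otab <- ordinal_summary(summ$ordinal, summ$conserved_fraction,
                          max_ordinal = cfg$max_ordinal)
  fvr <- if ("1" %in% names(otab$values) && length(otab$values) >= 2L)
    first_vs_rest_test(otab, alternative = "greater") else NULL

  ## first-intron per-gene table ------------------------------------------
  fi <- summ[summ$ordinal == 1L, , drop = FALSE]
  log_count("first_introns", nrow(fi), nrow(fi))

  cors <- lapply(names(peaks), function(m) {
    bk <- binned_kendall(fi$conserved_fraction, fi[[m]],
                         bin_size = cfg$bin_size_cons,
                         drop_zero_zero = cfg$drop_zero_zero)
    data.frame(mark = m, n_pairs = bk$n_used, n_bins = nrow(bk$series),
               tau_binned = bk$binned$tau, p_binned = bk$binned$p_value,
               tau_raw = bk$raw$tau, p_raw = bk$raw$p_value)
  })
  cors <- do.call(rbind, cors)

  ## exon-count regressions ------------------------------------------------
  nex <- vapply(transcripts, n_exons, integer(1))
  names(nex) <- vapply(transcripts, function(t) t$gene_id, character(1))
  regs <- lapply(seq_len(cfg$max_regression_ordinal), function(k) {
    sk <- summ[summ$ordinal == k, , drop = FALSE]
    r <- exon_group_regression(nex[sk$gene_id], sk$conserved_fraction)
    data.frame(ordinal = k, slope = r$slope, intercept = r$intercept,
               r_squared = r$r_squared, n_groups = r$n_groups)
  })
  regs <- do.call(rbind, regs)

  ## expression correlation ------------------------------------------------
  expr_cor <- NULL
  if (!is.null(expr_tab)) {
    cons_vec <- stats::setNames(fi$conserved_fraction, fi$gene_id)
    rows <- lapply(setdiff(names(expr_tab), "gene_id"), function(tis) {
      ev <- stats::setNames(expr_tab[[tis]], expr_tab$gene_id)
      ec <- expression_correlation(cons_vec, ev,
                                   bin_size = cfg$bin_size_expr,
                                   drop_zero_zero = cfg$drop_zero_zero)
      data.frame(tissue = tis, n_pairs = ec$n_used,
                 tau_binned = ec$binned$tau, p_binned = ec$binned$p_value,
                 tau_raw = ec$raw$tau, p_raw = ec$raw$p_value)
    })
    expr_cor <- do.call(rbind, rows)
  }

  ## gene-wise odds --------------------------------------------------------
  fi_regions <- regions[S4Vectors::mcols(regions)$ordinal == 1L]
  odds <- genewise_odds(fi_regions, track, peaks, threshold = thr,
                        alpha = cfg$alpha, sig_p = cfg$sig_p)
  tally <- cohort_tally(odds)

  ## controls --------------------------------------------------------------
  fi_introns <- introns[introns$ordinal == 1L, , drop = FALSE]
  prom_regions <- do.call(c, unname(lapply(
    fi_introns$transcript_id, function(tid) {
      t <- transcripts[[tid]]
      fr <- flank_regions(t, fcfg)
      up <- nostrand(fr[names(fr) == "upstream"])
      e1 <- if (t$strand == "+") {
        GenomicRanges::GRanges(t$chrom,
                               IRanges::IRanges(t$exon_start[1L], t$exon_end[1L]))
      } else {
        n <- n_exons(t)
        GenomicRanges::GRanges(t$chrom,
                               IRanges::IRanges(t$exon_start[n], t$exon_end[n]))
      }
      gr <- GenomicRanges::reduce(c(up, e1))
      S4Vectors::mcols(gr)$gene_id <- t$gene_id
      gr
    })))
  prom_summ <- region_summaries(prom_regions, peaks = peaks,
                                id_col = "gene_id")
  prom_summ <- prom_summ[match(fi_introns$gene_id, prom_summ$region_id), ,
                         drop = FALSE]
  fi_ord <- fi[match(fi_introns$gene_id, fi$gene_id), , drop = FALSE]
  spill <- lapply(names(peaks), function(m) {
    sf <- spillover_filter(fi_introns$gene_id, fi_ord[[m]], prom_summ[[m]])
    cbind(mark = m, sf$log)
  })
  spill <- do.call(rbind, spill)

  ovf <- overlap_filter(fi_introns, transcripts, flank = fcfg$flank_length)

  dist_by_id <- stats::setNames(tss_distance(introns, transcripts),
                                introns$intron_id)
  dists <- dist_by_id[summ$intron_id]
  first_d <- data.frame(distance = dists[summ$ordinal == 1L],
                        value = summ$conserved_fraction[summ$ordinal == 1L])
  second_d <- data.frame(distance = dists[summ$ordinal == 2L],
                         value = summ$conserved_fraction[summ$ordinal == 2L])
  tssm <- tss_matched_compare(first_d, second_d)

  pos <- lapply(names(peaks), function(m) {
    pb <- positional_bias(fi_introns, peaks[[m]], trim = fcfg$trim)
    data.frame(mark = m, bin = seq_along(pb$fraction_per_bin),
               fraction = pb$fraction_per_bin, n_introns = pb$n_introns,
               n_skipped = pb$n_skipped)
  })
  pos <- do.call(rbind, pos)

  counts_df <- do.call(rbind, counts)
  res <- list(counts = counts_df, introns = introns, summaries = summ,
              ordinal_table = otab$table, first_vs_rest = fvr,
              correlations = cors, exon_regression = regs,
              expression_correlation = expr_cor, odds = odds,
              odds_tally = tally, spillover = spill, overlap = ovf$log,
              tss_matched = tssm, positional_bias = pos)

  if (!is.null(cfg$outdir)) {
    dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
    hdr <- config_provenance(cfg)
    for (nm in c("counts", "ordinal_table", "first_vs_rest", "correlations",
                 "exon_regression", "expression_correlation", "odds",
                 "odds_tally", "spillover", "overlap", "tss_matched",
                 "positional_bias")) {
      if (!is.null(res[[nm]]))
        write_report_tsv(res[[nm]], file.path(cfg$outdir,
                                              paste0(nm, ".tsv")), hdr)
    }
    write_intron_tsv(introns, file.path(cfg$outdir, "introns.tsv"))
    write_report_tsv(summ, file.path(cfg$outdir, "summaries.tsv"), hdr)
  }
  res
}
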