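## Confounder-control procedures: promoter spillover exclusion, overlapping
## gene exclusion, TSS-distance-matched comparison, positional-bias scan.

#' Exclude genes whose promoter/first-exon signal matches the intron's
#'
#' A gene survives only when its first-intron coverage fraction is strictly
#' greater than the coverage of the pooled promoter + first-exon region
#' ("at least as high" promoter signal excludes, so equality excludes).
#' Genes with missing values are excluded and logged.
#'
#' @param gene_id Character vector of gene ids.
#' @param intron_fraction Per-gene first-intron coverage fraction of one
#'   mark.
#' @param promoter_fraction Per-gene coverage fraction of the pooled
#'   promoter (upstream flank) + first-exon region for the same mark.
#' @return A list with `kept` (surviving gene ids) and `log` (data.frame
#'   of all genes with values, decision and reason).
#' @export
spillover_filter <- function(gene_id, intron_fraction, promoter_fraction) {
  stopifnot(length(gene_id) == length(intron_fraction),
            length(gene_id) == length(promoter_fraction))
  missing <- is.na(intron_fraction) | is.na(promoter_fraction)
  keep <- !missing & intron_fraction > promoter_fraction
  reason <- ifelse(missing, "missing",
                   ifelse(keep, "", "promoter_at_least_as_high"))
  list(kept = gene_id[keep],
       log = data.frame(gene_id = gene_id,
                        intron_fraction = intron_fraction,
                        promoter_fraction = promoter_fraction,
                        kept = keep, reason = reason,
                        stringsAsFactors = FALSE))
}

#' Exclude genes whose first intron overlaps another gene's exons or flanks
#'
#' Removes genes whose first-intron raw interval intersects any exon, or
#' any flank (default 2 kb on both sides), of a *different* gene.
#'
#' @param first_introns Data.frame of first-intron rows (one per gene,
#'   with `gene_id`, `chrom`, `start`, `end`).
#' @param transcripts List of all `transcript_model`s (all genes, all
#'   transcripts).
#' @param flank Flank length in bases; default 2000.
#' @return A list with `kept` gene ids and an exclusion `log`.
#' @export
overlap_filter <- function(first_introns, transcripts, flank = 2000L) {
  feats <- lapply(transcripts, function(t) {
    sp <- transcript_span(t)
    s <- c(t$exon_start, max(1L, sp[1L] - flank), sp[2L] + 1L)
    e <- c(t$exon_end, sp[1L] - 1L, sp[2L] + flank)
    keep <- s <= e
    GenomicRanges::GRanges(t$chrom, IRanges::IRanges(s[keep], e[keep]),
                           gene_id = t$gene_id)
  })
  feat_gr <- do.call(c, unname(feats))
  fi_gr <- GenomicRanges::GRanges(first_introns$chrom,
                                  IRanges::IRanges(first_introns$start,
                                                   first_introns$end))
  ov <- GenomicRanges::findOverlaps(fi_gr, feat_gr, ignore.strand = TRUE)
  other <- first_introns$gene_id[S4Vectors::queryHits(ov)] !=
    S4Vectors::mcols(feat_gr)$gene_id[S4Vectors::subjectHits(ov)]
  hit_idx <- unique(S4Vectors::queryHits(ov)[other])
  removed <- logical(nrow(first_introns))
  removed[hit_idx] <- TRUE
  list(kept = first_introns$gene_id[!removed],
       log = data.frame(gene_id = first_introns$gene_id,
                        kept = !removed,
                        reason = ifelse(removed, "overlaps_other_gene", ""),
                        stringsAsFactors = FALSE))
}

#' Distance-bin specification for TSS-matched comparisons
#'
#' @param min_distance,max_distance Window of TSS distances (bases) in
#'   which first- and second-intron distributions overlap; defaults
#'   500-1000.
#' @param n_bins Number of equal-width bins; default 5 (100 bp each).
#' @return A list with `min`, `max` and the bin `edges`.
#' @export
distance_bins <- function(min_distance = 500L, max_distance = 1000L,
                          n_bins = 5L) {
  stopifnot(max_distance > min_distance, n_bins >= 1L)
  list(min = min_distance, max = max_distance,
       edges = seq(min_distance, max_distance, length.out = n_bins + 1L))
}

#' Compare first vs second introns within TSS-distance bins
#'
#' Only introns whose TSS distance falls inside the window enter (both
#' edges inclusive). Within each bin -- and once over the whole window
#' (`"overall"` row) -- first- and second-intron values are compared with a
#' one-sided (first > second) Wilcoxon rank-sum test. Bins with fewer than
#' `min_n` introns on either side are reported but not tested.
#'
#' @param first,second Data.frames with `distance` and `value` columns.
#' @param bins A [distance_bins()] specification.
#' @param alternative Test direction; default `"greater"`.
#' @param min_n Minimum per-side bin occupancy to test; default 3.
#' @return A data.frame with one row per bin plus an overall row: bin
#'   bounds, per-side n and medians, `p_value` and a `tested` flag.
#' @export
tss_matched_compare <- function(first, second, bins = distance_bins(),
                                alternative = "greater", min_n = 3L) {
  win <- function(df) {
    df <- df[!is.na(df$distance) & !is.na(df$value) &
               df$distance >= bins$min & df$distance <= bins$max, , drop = FALSE]
    df$bin <- findInterval(df$distance, bins$edges, rightmost.closed = TRUE)
    df
  }
  f <- win(first); s <- win(second)
  nb <- length(bins$edges) - 1L
  one_row <- function(label, lo, hi, a, b) {
    tested <- length(a) >= min_n && length(b) >= min_n
    data.frame(bin = label, lo = lo, hi = hi,
               n_first = length(a), n_second = length(b),
               median_first = if (length(a)) stats::median(a) else NA_real_,
               median_second = if (length(b)) stats::median(b) else NA_real_,
               p_value = if (tested) rank_sum_p(a, b, alternative) else NA_real_,
               tested = tested, stringsAsFactors = FALSE)
  }
  rows <- lapply(seq_len(nb), function(k) {
    one_row(sprintf("%g-%g", bins$edges[k], bins$edges[k + 1L]),
            bins$edges[k], bins$edges[k + 1L],
            f$value[f$bin == k], s$value[s$bin == k])
  })
  rows[[nb + 1L]] <- one_row("overall", bins$min, bins$max, f$value, s$value)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Positional-bias scan: where along the intron does the signal peak?
#'
#' Each intron's trimmed span (raw interval minus the end trims) is divided
#' into `n_bins` equal-length bins ordered 5' to 3' in transcript
#' orientation. Per intron the bin with the highest signal density
#' (covered-base fraction for peaks, mean score for a track) is recorded,
#' ties resolved toward the 5'-most bin; introns with no signal anywhere
#' are skipped and counted separately. Introns shorter than the cohort
#' median raw length are excluded first, so short introns cannot force
#' apparent 5' bias.
#'
#' @param introns Data.frame of (typically first-)intron rows with
#'   `chrom`, `start`, `end`, `strand`, `raw_length`.
#' @param signal Peak `GRanges`, or a score track (`GRanges` with a
#'   `score` column).
#' @param n_bins Number of bins; default 5.
#' @param trim End trim in bases matching the analysis trimming;
#'   default 300.
#' @param min_raw_length Length floor; `NULL` (default) uses the median
#'   raw length of the supplied cohort.
#' @return A list with `fraction_per_bin` (sums to 1 over non-skipped
#'   introns), `counts`, `n_introns` (scored), `n_skipped` (no signal),
#'   `n_short` (below the length floor).
#' @export
positional_bias <- function(introns, signal, n_bins = 5L, trim = 300L,
                            min_raw_length = NULL) {
  if (is.null(min_raw_length))
    min_raw_length <- stats::median(introns$raw_length)
  n_short <- sum(introns$raw_length < min_raw_length)
  introns <- introns[introns$raw_length >= min_raw_length, , drop = FALSE]
  ts <- introns$start + trim
  te <- introns$end - trim
  ok <- te - ts + 1L >= n_bins
  introns <- introns[ok, , drop = FALSE]
  ts <- ts[ok]; te <- te[ok]
  n <- nrow(introns)
  if (n == 0L) stop("no introns long enough for the positional-bias scan")

  # equal-length bins (the few leftover bases go to the 3'-most bin)
  w <- (te - ts + 1L) %/% n_bins
  bs <- rep(ts, each = n_bins) + (rep(w, each = n_bins) *
                                    rep(seq_len(n_bins) - 1L, n))
  be <- bs + rep(w, each = n_bins) - 1L
  be[seq(n_bins, n * n_bins, by = n_bins)] <- te
  bin_gr <- GenomicRanges::GRanges(rep(introns$chrom, each = n_bins),
                                   IRanges::IRanges(bs, be))
  is_track <- !is.null(S4Vectors::mcols(signal)$score)
  if (is_track) {
    s0 <- nostrand(signal)
    ov <- GenomicRanges::findOverlaps(bin_gr, s0)
    wgt <- GenomicRanges::width(GenomicRanges::pintersect(
      bin_gr[S4Vectors::queryHits(ov)], s0[S4Vectors::subjectHits(ov)])) *
      S4Vectors::mcols(signal)$score[S4Vectors::subjectHits(ov)]
    dens <- numeric(length(bin_gr))
    if (length(ov)) {
      agg <- rowsum(wgt, S4Vectors::queryHits(ov))
      dens[as.integer(rownames(agg))] <- agg[, 1L]
    }
    dens <- dens / GenomicRanges::width(bin_gr)
  } else {
    dens <- covered_width(bin_gr, signal) / GenomicRanges::width(bin_gr)
  }
  dmat <- matrix(dens, ncol = n_bins, byrow = TRUE)
  # 5'->3' orientation: reverse bin order for minus-strand introns
  rev_rows <- introns$strand == "-"
  dmat[rev_rows, ] <- dmat[rev_rows, n_bins:1, drop = FALSE]
  skipped <- rowSums(dmat) == 0
  argmax <- apply(dmat[!skipped, , drop = FALSE], 1L, which.max)  # 5'-most tie
  counts <- tabulate(argmax, nbins = n_bins)
  list(fraction_per_bin = counts / sum(counts), counts = counts,
       n_introns = sum(!skipped), n_skipped = sum(skipped),
       n_short = n_short)
}
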