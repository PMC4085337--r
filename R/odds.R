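## Gene-wise log-odds enrichment of a regulatory signal in conserved vs
## non-conserved bases of the first intron.
##
## Cell semantics (base counts, not peak counts):
##   SC signal-covered conserved bases    NC uncovered conserved bases
##   SN signal-covered non-conserved bases NN uncovered non-conserved bases

#' Build the 2x2 base-count contingency table for one region set
#'
#' Partitions the analysis bases of (typically) one first intron by
#' conservation call and by peak overlap, and counts bases in the four
#' cells. The cells always sum to the effective length.
#'
#' @param regions Analysis regions (`GRanges`) of one intron/gene.
#' @param track Conservation score track.
#' @param peaks Peak `GRanges` for one mark.
#' @param threshold Conservation call threshold.
#' @return A named numeric vector `c(SC, NC, SN, NN)`.
#' @export
build_table <- function(regions, track, peaks, threshold = 0.5) {
  parts <- partition_by_conservation(regions, track, threshold)
  cw <- sum(GenomicRanges::width(parts$conserved))
  nw <- sum(GenomicRanges::width(parts$nonconserved))
  sc <- sum(covered_width(parts$conserved, peaks))
  sn <- sum(covered_width(parts$nonconserved, peaks))
  c(SC = sc, NC = cw - sc, SN = sn, NN = nw - sn)
}

# batched tables: one row per id in `id_col`, one table per mark
build_tables <- function(regions, track, peaks, threshold = 0.5,
                         id_col = "gene_id") {
  ids <- as.character(S4Vectors::mcols(regions)[[id_col]])
  uid <- unique(ids)
  cons <- conserved_part(track, threshold)
  r0 <- nostrand(regions)

  ov <- GenomicRanges::findOverlaps(r0, cons)
  cpieces <- GenomicRanges::pintersect(r0[S4Vectors::queryHits(ov)],
                                       cons[S4Vectors::subjectHits(ov)])
  cids <- ids[S4Vectors::queryHits(ov)]
  nlist <- GenomicRanges::subtract(r0, cons)
  npieces <- unlist(nlist, use.names = FALSE)
  nids <- rep(ids, S4Vectors::elementNROWS(nlist))

  sum_by <- function(v, f) {
    s <- tapply(v, factor(f, levels = uid), sum)
    s[is.na(s)] <- 0
    as.numeric(s)
  }
  cw <- sum_by(GenomicRanges::width(cpieces), cids)
  nw <- sum_by(GenomicRanges::width(npieces), nids)
  out <- lapply(peaks, function(pk) {
    sc <- sum_by(covered_width(cpieces, pk), cids)
    sn <- sum_by(covered_width(npieces, pk), nids)
    data.frame(gene_id = uid, SC = sc, NC = cw - sc, SN = sn, NN = nw - sn,
               stringsAsFactors = FALSE)
  })
  names(out) <- names(peaks)
  out
}

#' Log-odds ratio with Woolf-type confidence interval and Wald p-value
#'
#' OR = (SC * NN) / (NC * SN) on base counts; the confidence interval is
#' log OR +/- z * sqrt(1/SC + 1/NC + 1/SN + 1/NN) and the p-value comes
#' from the Wald z on the log scale. Tables with any zero cell get the
#' Haldane-Anscombe 0.5 correction (flagged); tables with two or more zero
#' cells (e.g. an intron with no conserved bases at all) are degenerate and
#' return `NA` sentinels.
#'
#' @param tbl Either a named vector `c(SC, NC, SN, NN)` or a data.frame
#'   with those columns (vectorized over rows).
#' @param alpha Confidence level complement; default 0.05 (95% CI).
#' @param sig_p Significance threshold for the `significant` flag;
#'   default 0.01.
#' @return A data.frame with `log_odds`, `ci_low`, `ci_high`, `p_value`,
#'   `significant`, `corrected`, `degenerate` (plus any input id columns).
#' @export
odds_ratio <- function(tbl, alpha = 0.05, sig_p = 0.01) {
  if (is.numeric(tbl) && !is.data.frame(tbl)) {
    tbl <- as.data.frame(as.list(tbl))
  }
  stopifnot(all(c("SC", "NC", "SN", "NN") %in% names(tbl)))
  cells <- as.matrix(tbl[, c("SC", "NC", "SN", "NN")])
  stopifnot(all(cells >= 0))
  nzero <- rowSums(cells == 0)
  degenerate <- nzero >= 2L
  corrected <- nzero == 1L
  cc <- cells + 0.5 * (nzero > 0L)
  lo <- log(cc[, "SC"]) + log(cc[, "NN"]) - log(cc[, "NC"]) - log(cc[, "SN"])
  se <- sqrt(rowSums(1 / cc))
  z <- stats::qnorm(1 - alpha / 2)
  p <- 2 * stats::pnorm(-abs(lo / se))
  res <- data.frame(log_odds = lo, ci_low = lo - z * se, ci_high = lo + z * se,
                    p_value = p, significant = p < sig_p,
                    corrected = corrected, degenerate = degenerate)
  res[degenerate, c("log_odds", "ci_low", "ci_high", "p_value")] <- NA_real_
  res$significant[degenerate] <- NA
  idcols <- setdiff(names(tbl), c("SC", "NC", "SN", "NN"))
  if (length(idcols)) res <- cbind(tbl[, idcols, drop = FALSE], res)
  rownames(res) <- NULL
  res
}

#' Gene-wise log-odds enrichment for every mark
#'
#' Runs [build_table()] logic in batch over all genes' first-intron
#' analysis regions and applies [odds_ratio()] per mark.
#'
#' @param regions Analysis regions `GRanges` with a `gene_id` metadata
#'   column (typically the first-intron regions of the cohort).
#' @param track Conservation score track.
#' @param peaks Named list of peak `GRanges`, one per mark.
#' @param threshold Conservation call threshold.
#' @param alpha,sig_p Passed to [odds_ratio()].
#' @return A data.frame with one row per gene x mark: ids, the four cells
#'   and the [odds_ratio()] columns.
#' @export
genewise_odds <- function(regions, track, peaks, threshold = 0.5,
                          alpha = 0.05, sig_p = 0.01) {
  tabs <- build_tables(regions, track, peaks, threshold)
  out <- lapply(names(tabs), function(m) {
    cbind(mark = m, odds_ratio(tabs[[m]], alpha = alpha, sig_p = sig_p),
          tabs[[m]][, c("SC", "NC", "SN", "NN")])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Tally significant gene-wise enrichments per mark
#'
#' @param results A [genewise_odds()] data.frame.
#' @return A data.frame per mark: `n_total` (non-degenerate genes tested),
#'   `n_sig_positive`, `n_sig_negative`.
#' @export
cohort_tally <- function(results) {
  marks <- unique(results$mark)
  rows <- lapply(marks, function(m) {
    r <- results[results$mark == m & !results$degenerate, , drop = FALSE]
    data.frame(mark = m, n_total = nrow(r),
               n_sig_positive = sum(r$significant & r$log_odds > 0),
               n_sig_negative = sum(r$significant & r$log_odds < 0))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
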