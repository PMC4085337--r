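## Conservation / peak coverage overlays.
## All set arithmetic is strand-blind interval math on GRanges.

nostrand <- function(gr) {
  gr <- GenomicRanges::granges(gr)
  GenomicRanges::strand(gr) <- "*"
  gr
}

# per-element count of bases of `x` covered by (reduced) `subject`
covered_width <- function(x, subject) {
  out <- integer(length(x))
  if (length(x) == 0L || length(subject) == 0L) return(out)
  x0 <- nostrand(x)
  s0 <- GenomicRanges::reduce(nostrand(subject))
  ov <- GenomicRanges::findOverlaps(x0, s0)
  if (length(ov) == 0L) return(out)
  w <- GenomicRanges::width(GenomicRanges::pintersect(
    x0[S4Vectors::queryHits(ov)], s0[S4Vectors::subjectHits(ov)]))
  agg <- rowsum(w, S4Vectors::queryHits(ov))
  out[as.integer(rownames(agg))] <- agg[, 1L]
  out
}

conserved_part <- function(track, threshold) {
  GenomicRanges::reduce(
    nostrand(track[S4Vectors::mcols(track)$score >= threshold]))
}

#' Fraction of bases called conserved in a region set
#'
#' A base is conserved when its track score is at or above the threshold
#' (inclusive); bases absent from the track score 0. Returns `NA` when the
#' region set is empty (never 0/0 = 0).
#'
#' @param regions Disjoint `GRanges` to evaluate.
#' @param track Score track `GRanges` (metadata column `score` in \[0, 1\]).
#' @param threshold Conservation call threshold in (0, 1\]; default 0.5.
#' @return A fraction in \[0, 1\], or `NA_real_` for an empty region set.
#' @export
conserved_fraction <- function(regions, track, threshold = 0.5) {
  total <- sum(GenomicRanges::width(regions))
  if (total == 0L) return(NA_real_)
  sum(covered_width(regions, conserved_part(track, threshold))) / total
}

#' Fraction of bases covered by a peak set
#'
#' @param regions Disjoint `GRanges` to evaluate.
#' @param peaks Peak `GRanges` (merged internally if overlapping).
#' @return Overlapping bases / total bases, or `NA_real_` if the region
#'   set is empty.
#' @export
coverage_fraction <- function(regions, peaks) {
  total <- sum(GenomicRanges::width(regions))
  if (total == 0L) return(NA_real_)
  sum(covered_width(regions, peaks)) / total
}

#' Split a region set into conserved and non-conserved bases
#'
#' Produces a disjoint, exhaustive partition: every input base lands in
#' exactly one of the two outputs.
#'
#' @inheritParams conserved_fraction
#' @return A list with `conserved` and `nonconserved` `GRanges`.
#' @export
partition_by_conservation <- function(regions, track, threshold = 0.5) {
  r <- GenomicRanges::reduce(nostrand(regions))
  cons <- conserved_part(track, threshold)
  list(conserved = GenomicRanges::intersect(r, cons),
       nonconserved = GenomicRanges::setdiff(r, cons))
}

#' Summarize conservation and signal coverage per region group
#'
#' Batched counterpart of [conserved_fraction()] / [coverage_fraction()]:
#' regions sharing an id (e.g. the analysis regions of one intron) are
#' pooled and one row of fractions is produced per id.
#'
#' @param regions `GRanges` whose metadata holds the grouping ids.
#' @param track Optional score track; adds a `conserved_fraction` column.
#' @param peaks Named list of peak `GRanges`; adds one column per mark.
#' @param threshold Conservation call threshold.
#' @param id_col Name of the metadata column holding the region ids.
#' @return A data.frame with `region_id`, `effective_length`,
#'   `conserved_fraction` (if a track is given) and one coverage column per
#'   mark. Fractions are `NA` for ids with zero total bases.
#' @export
region_summaries <- function(regions, track = NULL, peaks = list(),
                             threshold = 0.5, id_col = "intron_id") {
  ids <- as.character(S4Vectors::mcols(regions)[[id_col]])
  uid <- unique(ids)
  f <- factor(ids, levels = uid)
  sum_by <- function(v) {
    s <- tapply(v, f, sum)
    s[is.na(s)] <- 0
    as.numeric(s)
  }
  tot <- sum_by(GenomicRanges::width(regions))
  out <- data.frame(region_id = uid, effective_length = as.integer(tot),
                    stringsAsFactors = FALSE)
  frac <- function(v) ifelse(tot > 0, v / tot, NA_real_)
  if (!is.null(track)) {
    cons <- conserved_part(track, threshold)
    out$conserved_fraction <- frac(sum_by(covered_width(regions, cons)))
  }
  for (m in names(peaks)) {
    out[[m]] <- frac(sum_by(covered_width(regions, peaks[[m]])))
  }
  out
}
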