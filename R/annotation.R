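#' Analysis filter configuration
#'
#' Bundles the filtering rules applied to introns before any conservation or
#' signal overlay: a hard length floor, a boxplot-style outlier ceiling
#' (Q3 + k * IQR on the pooled post-floor cohort), splice-proximal trimming,
#' the conservation score threshold, and the flank length used for
#' promoter/downstream regions.
#'
#' @param min_intron_length Minimum raw intron length in bases; shorter
#'   introns are excluded outright. Default 1000.
#' @param trim Bases removed from each intron end before analysis, to keep
#'   splice-regulatory sequence out of the conservation estimates.
#'   Default 300.
#' @param outlier_k Multiplier on the interquartile range for the long-intron
#'   ceiling (Q3 + k * IQR). Default 1.5.
#' @param conservation_threshold Per-base score at or above which a base is
#'   called conserved (inclusive). Default 0.5.
#' @param flank_length Length in bases of the upstream/downstream flanking
#'   regions. Default 2000.
#' @param quantile_type Quantile algorithm used for Q1/Q3 (passed to
#'   [stats::quantile()]); type 7 is linear interpolation between order
#'   statistics, recorded here so the outlier filter is bit-reproducible.
#' @param repeat_mode `"mask"` subtracts repeat bases from the analysis
#'   regions; `"drop"` discards any intron whose raw interval overlaps a
#'   repeat at all.
#' @return A `filter_config` list.
#' @export
filter_config <- function(min_intron_length = 1000L, trim = 300L,
                          outlier_k = 1.5, conservation_threshold = 0.5,
                          flank_length = 2000L, quantile_type = 7L,
                          repeat_mode = c("mask", "drop")) {
  repeat_mode <- match.arg(repeat_mode)
  stopifnot(min_intron_length > 0, trim > 0,
            2L * trim < min_intron_length,
            outlier_k > 0,
            conservation_threshold > 0, conservation_threshold <= 1,
            flank_length > 0)
  structure(list(min_intron_length = as.integer(min_intron_length),
                 trim = as.integer(trim),
                 outlier_k = outlier_k,
                 conservation_threshold = conservation_threshold,
                 flank_length = as.integer(flank_length),
                 quantile_type = as.integer(quantile_type),
                 repeat_mode = repeat_mode),
            class = "filter_config")
}

#' Construct a transcript model
#'
#' A transcript is an ordered chain of exons on one chromosome and strand.
#' Coordinates are 1-based closed (the GRanges convention); BED input is
#' converted at the IO boundary. Exons must be non-overlapping and
#' non-adjacent (a zero-length gap would imply an empty intron).
#'
#' @param transcript_id,gene_id Identifiers.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exon_start,exon_end Parallel integer vectors of exon coordinates
#'   (1-based, closed); sorted internally by start.
#' @return A `transcript_model` object.
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand,
                             exon_start, exon_end) {
  exon_start <- as.integer(exon_start)
  exon_end <- as.integer(exon_end)
  stopifnot(length(transcript_id) == 1L, length(gene_id) == 1L,
            length(chrom) == 1L, length(strand) == 1L,
            strand %in% c("+", "-"),
            length(exon_start) >= 1L,
            length(exon_start) == length(exon_end),
            all(exon_start >= 1L), all(exon_end >= exon_start))
  o <- order(exon_start)
  exon_start <- exon_start[o]
  exon_end <- exon_end[o]
  n <- length(exon_start)
  if (n > 1L && any(exon_start[-1L] <= exon_end[-n] + 1L))
    stop("exons overlap or are adjacent in transcript ", transcript_id)
  structure(list(transcript_id = as.character(transcript_id),
                 gene_id = as.character(gene_id),
                 chrom = as.character(chrom),
                 strand = strand,
                 exon_start = exon_start,
                 exon_end = exon_end),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("transcript_model %s (gene %s) %s:%d-%d (%s), %d exon(s)\n",
              x$transcript_id, x$gene_id, x$chrom,
              min(x$exon_start), max(x$exon_end), x$strand,
              length(x$exon_start)))
  invisible(x)
}

n_exons <- function(t) length(t$exon_start)

transcript_span <- function(t) c(min(t$exon_start), max(t$exon_end))

empty_intron_df <- function() {
  data.frame(transcript_id = character(0), gene_id = character(0),
             chrom = character(0), strand = character(0),
             start = integer(0), end = integer(0), ordinal = integer(0),
             raw_length = integer(0), stringsAsFactors = FALSE)
}

#' Extract introns with ordinal positions
#'
#' Introns are the gaps between consecutive exons. Ordinals count from the
#' transcript's 5' end: on the minus strand the intron with the greatest
#' genomic coordinates is ordinal 1.
#'
#' @param x A `transcript_model` or a list of them.
#' @return A data.frame with one row per intron: `transcript_id`, `gene_id`,
#'   `chrom`, `strand`, `start`, `end` (1-based closed), `ordinal`,
#'   `raw_length`. A single-exon transcript contributes no rows.
#' @export
extract_introns <- function(x) {
  if (inherits(x, "transcript_model")) x <- list(x)
  res <- lapply(x, function(t) {
    n <- length(t$exon_start)
    if (n < 2L) return(NULL)
    s <- t$exon_end[-n] + 1L
    e <- t$exon_start[-1L] - 1L
    ord <- if (t$strand == "+") seq_len(n - 1L) else rev(seq_len(n - 1L))
    data.frame(transcript_id = t$transcript_id, gene_id = t$gene_id,
               chrom = t$chrom, strand = t$strand,
               start = s, end = e, ordinal = as.integer(ord),
               raw_length = e - s + 1L, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(res, list(empty_intron_df())))
  rownames(out) <- NULL
  out
}

#' Filter introns by length floor and pooled outlier ceiling
#'
#' Removes introns shorter than the floor, then computes Q3 and IQR of the
#' raw lengths of the *surviving* cohort (pooled across all ordinals) and
#' removes introns strictly longer than Q3 + k * IQR. The ceiling boundary
#' is inclusive: with zero IQR, introns exactly at Q3 are retained.
#'
#' @param introns Intron data.frame from [extract_introns()].
#' @param cfg A [filter_config()].
#' @return The surviving rows, original order preserved.
#' @export
filter_introns <- function(introns, cfg = filter_config()) {
  if (nrow(introns) == 0L) return(introns)
  surv <- introns[introns$raw_length >= cfg$min_intron_length, , drop = FALSE]
  if (nrow(surv) > 0L) {
    q <- stats::quantile(surv$raw_length, c(0.25, 0.75),
                         type = cfg$quantile_type, names = FALSE)
    ceiling_len <- q[2L] + cfg$outlier_k * (q[2L] - q[1L])
    surv <- surv[surv$raw_length <= ceiling_len, , drop = FALSE]
  }
  rownames(surv) <- NULL
  surv
}

#' Trim intron ends and subtract repeat-masked bases
#'
#' Shrinks each raw intron by `cfg$trim` bases at both genomic ends, then
#' removes all bases overlapping the mask, leaving a minimal sorted set of
#' disjoint analysis regions per intron. In `repeat_mode = "drop"` any
#' intron whose raw interval overlaps the mask is excluded entirely.
#'
#' @param introns Intron data.frame (post-filter).
#' @param mask A [GenomicRanges::GRanges] of repeat intervals (may be empty).
#' @param cfg A [filter_config()].
#' @return A list with `introns` (input rows plus `intron_id`,
#'   `effective_length`, `n_regions`, `excluded`) and `regions`, a `GRanges`
#'   of all analysis regions carrying `intron_id`, `transcript_id`,
#'   `gene_id`, `ordinal` metadata.
#' @export
trim_and_mask <- function(introns, mask = GenomicRanges::GRanges(),
                          cfg = filter_config()) {
  introns$intron_id <- if (nrow(introns)) {
    paste0(introns$transcript_id, ":", introns$ordinal)
  } else character(0)
  introns$effective_length <- integer(nrow(introns))
  introns$n_regions <- integer(nrow(introns))
  introns$excluded <- logical(nrow(introns))
  if (nrow(introns) == 0L) {
    return(list(introns = introns, regions = GenomicRanges::GRanges()))
  }

  if (cfg$repeat_mode == "drop" && length(mask) > 0L) {
    raw_gr <- GenomicRanges::GRanges(introns$chrom,
                                     IRanges::IRanges(introns$start, introns$end))
    hit <- IRanges::overlapsAny(raw_gr, mask, ignore.strand = TRUE)
    introns$excluded <- introns$excluded | hit
  }

  ts <- introns$start + cfg$trim
  te <- introns$end - cfg$trim
  valid <- ts <= te & !introns$excluded
  if (!any(valid)) {
    introns$excluded <- TRUE
    return(list(introns = introns, regions = GenomicRanges::GRanges()))
  }

  trimmed <- GenomicRanges::GRanges(introns$chrom[valid],
                                    IRanges::IRanges(ts[valid], te[valid]),
                                    strand = introns$strand[valid])
  if (cfg$repeat_mode == "mask" && length(mask) > 0L) {
    pieces <- GenomicRanges::subtract(trimmed, mask, ignore.strand = TRUE)
  } else {
    pieces <- methods::as(trimmed, "GRangesList")
  }
  npc <- S4Vectors::elementNROWS(pieces)
  regions <- unlist(pieces, use.names = FALSE)
  idx <- rep(which(valid), npc)
  S4Vectors::mcols(regions)$intron_id <- introns$intron_id[idx]
  S4Vectors::mcols(regions)$transcript_id <- introns$transcript_id[idx]
  S4Vectors::mcols(regions)$gene_id <- introns$gene_id[idx]
  S4Vectors::mcols(regions)$ordinal <- introns$ordinal[idx]

  eff <- tapply(GenomicRanges::width(regions),
                factor(S4Vectors::mcols(regions)$intron_id,
                       levels = introns$intron_id), sum)
  eff[is.na(eff)] <- 0L
  introns$effective_length <- as.integer(eff)
  nr <- table(factor(S4Vectors::mcols(regions)$intron_id,
                     levels = introns$intron_id))
  introns$n_regions <- as.integer(nr)
  introns$excluded <- introns$excluded | introns$effective_length == 0L
  list(introns = introns, regions = regions)
}

#' Upstream and downstream flanking regions of a transcript
#'
#' The upstream flank is the `flank_length` bases 5' of the first exon in
#' transcript orientation (a promoter proxy); the downstream flank sits 3'
#' of the last exon. Both are clipped at chromosome position 1.
#'
#' @param t A `transcript_model`.
#' @param cfg A [filter_config()].
#' @return A `GRanges` of length two named `upstream`, `downstream`
#'   (upstream may have zero width if the transcript starts at the
#'   chromosome edge and is dropped in that degenerate case).
#' @export
flank_regions <- function(t, cfg = filter_config()) {
  fl <- cfg$flank_length
  span <- transcript_span(t)
  if (t$strand == "+") {
    up <- c(max(1L, span[1L] - fl), span[1L] - 1L)
    dn <- c(span[2L] + 1L, span[2L] + fl)
  } else {
    up <- c(span[2L] + 1L, span[2L] + fl)
    dn <- c(max(1L, span[1L] - fl), span[1L] - 1L)
  }
  keep <- c(up[1L] <= up[2L], dn[1L] <= dn[2L])
  gr <- GenomicRanges::GRanges(
    t$chrom,
    IRanges::IRanges(c(up[1L], dn[1L])[keep], c(up[2L], dn[2L])[keep]),
    strand = t$strand)
  names(gr) <- c("upstream", "downstream")[keep]
  gr
}

#' Genomic distance from the TSS to an intron's 5' boundary
#'
#' Uses the start of the first exon (in transcript orientation) as the TSS
#' proxy and measures the unspliced genomic distance to the intron's 5'
#' end, so the ordinal-1 distance equals the first-exon length.
#'
#' @param introns Intron data.frame.
#' @param transcripts A list of `transcript_model`s (named or not; matched
#'   by `transcript_id`).
#' @return Integer vector of non-negative distances, parallel to
#'   `introns` rows.
#' @export
tss_distance <- function(introns, transcripts) {
  if (inherits(transcripts, "transcript_model"))
    transcripts <- list(transcripts)
  ids <- vapply(transcripts, function(t) t$transcript_id, character(1))
  names(transcripts) <- ids
  vapply(seq_len(nrow(introns)), function(i) {
    t <- transcripts[[introns$transcript_id[i]]]
    if (is.null(t)) stop("transcript not found: ", introns$transcript_id[i])
    if (t$strand == "+") {
      introns$start[i] - min(t$exon_start)
    } else {
      max(t$exon_end) - introns$end[i]
    }
  }, integer(1))
}

#' Choose one representative transcript per gene
#'
#' Deterministic rule: most exons, ties broken by longest genomic span,
#' then by lexicographically smallest transcript id. The underlying data
#' offer no principled choice, so the rule is a declared convention.
#'
#' @param transcripts A non-empty list of `transcript_model`s of one gene.
#' @return A single `transcript_model`.
#' @export
select_representative <- function(transcripts) {
  stopifnot(length(transcripts) >= 1L)
  if (length(transcripts) == 1L) return(transcripts[[1L]])
  ne <- vapply(transcripts, n_exons, integer(1))
  sp <- vapply(transcripts, function(t) diff(transcript_span(t)) + 1L, integer(1))
  id <- vapply(transcripts, function(t) t$transcript_id, character(1))
  o <- order(-ne, -sp, id)
  transcripts[[o[1L]]]
}
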