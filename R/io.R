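#' Read gene models from GTF/GFF
#'
#' Keeps `exon` features, groups them by `transcript_id` and builds one
#' `transcript_model` per transcript. GTF's 1-based closed coordinates are
#' the internal convention, so no shift is applied.
#'
#' @param path Path to a GTF/GFF file with exon features carrying
#'   `transcript_id` (and ideally `gene_id`) attributes.
#' @return A named list of `transcript_model`s.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path)
  mc <- S4Vectors::mcols(gr)
  if ("type" %in% names(mc)) gr <- gr[as.character(mc$type) == "exon"]
  mc <- S4Vectors::mcols(gr)
  tid <- as.character(mc$transcript_id)
  gid <- if ("gene_id" %in% names(mc)) as.character(mc$gene_id) else tid
  build_models(as.character(GenomicRanges::seqnames(gr)),
               GenomicRanges::start(gr), GenomicRanges::end(gr),
               as.character(GenomicRanges::strand(gr)), tid, gid)
}

#' Read gene models from BED12
#'
#' Blocks become exons; the BED name column is used as both transcript and
#' gene id. Coordinates are converted from 0-based half-open on import.
#'
#' @param path Path to a BED12 file.
#' @return A named list of `transcript_model`s.
#' @export
read_bed12_models <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  blocks <- S4Vectors::mcols(gr)$blocks
  if (is.null(blocks)) stop("not a BED12 file (no blocks): ", path)
  out <- vector("list", length(gr))
  for (i in seq_along(gr)) {
    b <- IRanges::shift(blocks[[i]], GenomicRanges::start(gr)[i] - 1L)
    nm <- S4Vectors::mcols(gr)$name[i]
    out[[i]] <- transcript_model(nm, nm,
                                 as.character(GenomicRanges::seqnames(gr))[i],
                                 as.character(GenomicRanges::strand(gr))[i],
                                 IRanges::start(b), IRanges::end(b))
  }
  names(out) <- vapply(out, function(t) t$transcript_id, character(1))
  out
}

build_models <- function(chrom, start, end, strand, transcript_id, gene_id) {
  idx <- split(seq_along(transcript_id), transcript_id)
  out <- lapply(idx, function(i) {
    transcript_model(transcript_id[i[1L]], gene_id[i[1L]],
                     chrom[i[1L]], strand[i[1L]], start[i], end[i])
  })
  out[order(names(out))]
}

#' Read a per-base conservation score track
#'
#' Accepts bedGraph (`.bedGraph`, `.bg`) or fixed/variable-step wiggle
#' (`.wig`). Scores must lie in \[0, 1\]; bases absent from the track have
#' implicit score 0 (unaligned bases are simply missing from such tracks).
#'
#' @param path Track file path.
#' @return A sorted `GRanges` with a `score` metadata column.
#' @export
read_score_track <- function(path) {
  fmt <- if (grepl("\\.wig(\\.gz)?$", path, ignore.case = TRUE)) "wig" else "bedGraph"
  gr <- rtracklayer::import(path, format = fmt)
  sc <- S4Vectors::mcols(gr)$score
  if (any(sc < 0 | sc > 1)) stop("scores outside [0, 1] in ", path)
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' Read peak intervals for one mark
#'
#' Accepts BED3+ or ENCODE narrowPeak files (columns beyond
#' chrom/start/end are ignored). Multiple files (replicates) are merged by
#' union, and overlapping peaks within a set are always merged.
#'
#' @param paths One or more file paths.
#' @param mark,cell_line Optional labels stored in the object metadata.
#' @return A reduced (disjoint, sorted) `GRanges`.
#' @export
read_peaks <- function(paths, mark = NA_character_, cell_line = NA_character_) {
  np_cols <- c(signalValue = "numeric", pValue = "numeric",
               qValue = "numeric", peak = "integer")
  grs <- lapply(paths, function(p) {
    if (file.size(p) == 0) return(GenomicRanges::GRanges())
    if (grepl("\\.narrowPeak(\\.gz)?$", p, ignore.case = TRUE)) {
      rtracklayer::import(p, format = "BED", extraCols = np_cols)
    } else {
      rtracklayer::import(p, format = "BED")
    }
  })
  gr <- GenomicRanges::reduce(do.call(c, lapply(grs, GenomicRanges::granges)),
                              ignore.strand = TRUE)
  S4Vectors::metadata(gr) <- list(mark = mark, cell_line = cell_line)
  gr
}

#' Read a BED file of plain intervals (e.g. a repeat mask)
#'
#' @param path BED file path.
#' @return A reduced `GRanges`.
#' @export
read_mask <- function(path) {
  if (file.size(path) == 0) return(GenomicRanges::GRanges())
  GenomicRanges::reduce(
    GenomicRanges::granges(rtracklayer::import(path, format = "BED")),
    ignore.strand = TRUE)
}

#' Read a gene expression table
#'
#' A TSV whose first column is the gene id and remaining columns are
#' per-tissue expression values. Values are expected on the log2(RPKM + 1)
#' scale; pass `log2p1 = TRUE` to transform raw RPKM on read.
#'
#' @param path TSV path.
#' @param log2p1 Apply `log2(x + 1)` to the values.
#' @return A data.frame with a `gene_id` column and numeric tissue columns.
#' @export
read_expression <- function(path, log2p1 = FALSE) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1L] <- "gene_id"
  for (j in seq(2L, ncol(df))) {
    df[[j]] <- as.numeric(df[[j]])
    if (log2p1) df[[j]] <- log2(df[[j]] + 1)
  }
  df
}

#' Write an intron table as TSV
#'
#' Coordinates are emitted 0-based half-open (BED convention) so the file
#' aligns with the interval formats the rest of the pipeline consumes.
#'
#' @param introns Intron data.frame (after [trim_and_mask()]).
#' @param path Output path.
#' @export
write_intron_tsv <- function(introns, path) {
  out <- data.frame(transcript_id = introns$transcript_id,
                    gene_id = introns$gene_id,
                    ordinal = introns$ordinal,
                    chrom = introns$chrom,
                    start = introns$start - 1L,
                    end = introns$end,
                    strand = introns$strand,
                    raw_length = introns$raw_length,
                    effective_length = introns$effective_length,
                    n_analysis_regions = introns$n_regions)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# internal writers (0-based half-open on disk)

write_bed6 <- function(gr, path, name = ".", score = 0L) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   name = name, score = score,
                   strand = sub("\\*", ".", as.character(GenomicRanges::strand(gr))))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

write_bedgraph <- function(gr, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   score = format(S4Vectors::mcols(gr)$score,
                                  trim = TRUE, scientific = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

write_gtf <- function(transcripts, path) {
  lines <- unlist(lapply(transcripts, function(t) {
    sprintf('%s\tsim\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
            t$chrom, t$exon_start, t$exon_end, t$strand, t$gene_id,
            t$transcript_id)
  }), use.names = FALSE)
  writeLines(lines, path)
  invisible(path)
}
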