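## Synthetic-genome generator with planted effects.
##
## Emits a complete input bundle (gene models, conservation track, repeat
## mask, per-mark peak sets, expression table) plus a truth record
## sufficient to score parameter recovery. Inside first-intron trimmed
## spans, peak coverage is realized base-by-base with two rates (high on
## conserved bases, low elsewhere) so the planted log-odds is exact and
## base counts are independent draws; elsewhere peaks are placed as
## mark-specific-width blocks.

#' Default regulatory-mark models
#'
#' Background coverage rate, planted log-odds of placement on conserved
#' first-intron bases, and typical peak width per mark. Active marks (DHS,
#' TFBS, H3K4me3) carry positive planted log-odds; H3K4me1 a weaker one;
#' the repressive H3K9me3 and the insulator CTCF are flat. Widths are
#' narrow for DHS/TFBS/H3K4me3 and broad for H3K4me1/H3K9me3.
#'
#' @return A data.frame with columns `mark`, `background`, `log_odds`,
#'   `width`.
#' @export
default_marks <- function() {
  data.frame(
    mark = c("DHS", "TFBS", "H3K4me3", "H3K4me1", "H3K9me3", "CTCF"),
    background = c(0.05, 0.03, 0.04, 0.10, 0.10, 0.03),
    log_odds = c(1.0, 1.0, 0.8, 0.4, 0.0, 0.0),
    width = c(150, 120, 300, 600, 800, 200),
    stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Parameters of the synthetic cohort. Defaults encode the structure the
#' analysis assumes: multi-exon genes (2-25 exons), first introns longest,
#' per-ordinal conserved-fraction targets decaying over ordinals 1-4, an
#' exon-count coupling acting on first-intron conservation only, a planted
#' Kendall tau between expression and realized first-intron conservation,
#' and per-mark log-odds of peak placement on conserved first-intron
#' bases. `null = TRUE` zeroes every planted effect (flat conservation
#' across ordinals, all mark log-odds 0, no couplings).
#'
#' @param n_genes Number of primary genes.
#' @param seed RNG seed (mandatory; the bundle is deterministic given it).
#' @param null Zero all planted effects.
#' @param chrom Synthetic chromosome name.
#' @param exon_count_mu,exon_count_size Negative-binomial model of exon
#'   counts, truncated to `exon_count_range`.
#' @param exon_count_range Allowed exon counts; default 2-25.
#' @param exon_meanlog,exon_sdlog Log-normal internal/last exon lengths.
#' @param exon1_meanlog,exon1_sdlog Log-normal first-exon length (controls
#'   the TSS distance of first introns).
#' @param intron_meanlog Named log-scale locations for intron lengths by
#'   ordinal (`first`, `second`, `third`, `rest`).
#' @param intron_sdlog Log-scale spread of intron lengths.
#' @param short_first_prob Fraction of genes drawn from a short-first-
#'   intron regime (sub-kilobase first introns whose *second* introns fall
#'   in the 500-1000 bp TSS-distance window).
#' @param short_exon1_meanlog,short_intron1_meanlog,short_sdlog Length
#'   model of that regime.
#' @param cons_levels Target conserved fractions for ordinals 1-3 and
#'   (4th value) all higher ordinals.
#' @param cons_block_mean Mean conserved block length in bases.
#' @param cons_noise_rate Density of sub-threshold score blocks.
#' @param flank_cons Conserved fraction of upstream flanks.
#' @param exon_coupling Linear modulation of the ordinal-1 target by exon
#'   count (`c1 * (1 + coupling * (n_exons - mean))`).
#' @param tau_expr Planted Kendall tau between expression and realized
#'   first-intron conservation (Gaussian copula).
#' @param tissues Pseudo-tissue names for the expression table.
#' @param marks Mark model data.frame, see [default_marks()].
#' @param flank_peak_scale Multiplier on background peak rates in flank +
#'   first-exon regions (0 gives signal-free promoters).
#' @param repeat_density,repeat_mean_len Repeat-mask coverage and mean
#'   element length.
#' @param intergenic Mean intergenic gap (a 4.5 kb floor keeps neighbouring
#'   flanks disjoint unless overlaps are requested).
#' @param n_overlap_genes Number of small genes planted inside host first
#'   introns to exercise the overlap filter.
#' @param trim End trim the downstream analysis will apply; the per-base
#'   peak process operates on the trimmed span.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 2000L, seed, null = FALSE,
                       chrom = "chrS1",
                       exon_count_mu = 8, exon_count_size = 2.5,
                       exon_count_range = c(2L, 25L),
                       exon_meanlog = log(160), exon_sdlog = 0.5,
                       exon1_meanlog = log(600), exon1_sdlog = 0.5,
                       intron_meanlog = c(first = log(7000),
                                          second = log(3500),
                                          third = log(2500),
                                          rest = log(1800)),
                       intron_sdlog = 0.4,
                       short_first_prob = 0.15,
                       short_exon1_meanlog = log(250),
                       short_intron1_meanlog = log(350),
                       short_sdlog = 0.3,
                       cons_levels = c(0.08, 0.05, 0.03, 0.02),
                       cons_block_mean = 60,
                       cons_noise_rate = 0.03,
                       flank_cons = 0.04,
                       exon_coupling = 0.08,
                       tau_expr = 0.3,
                       tissues = c("brain", "liver", "muscle", "testis"),
                       marks = default_marks(),
                       flank_peak_scale = 1,
                       repeat_density = 0.05, repeat_mean_len = 300,
                       intergenic = 8000L,
                       n_overlap_genes = 0L,
                       trim = 300L) {
  if (missing(seed)) stop("a seed is mandatory")
  if (null) {
    cons_levels <- rep(0.05, 4)
    exon_coupling <- 0
    tau_expr <- 0
    marks$log_odds <- 0
  }
  cfg <- list(n_genes = as.integer(n_genes), seed = as.integer(seed),
              null = null, chrom = chrom,
              exon_count_mu = exon_count_mu, exon_count_size = exon_count_size,
              exon_count_range = as.integer(exon_count_range),
              exon_meanlog = exon_meanlog, exon_sdlog = exon_sdlog,
              exon1_meanlog = exon1_meanlog, exon1_sdlog = exon1_sdlog,
              intron_meanlog = intron_meanlog, intron_sdlog = intron_sdlog,
              short_first_prob = short_first_prob,
              short_exon1_meanlog = short_exon1_meanlog,
              short_intron1_meanlog = short_intron1_meanlog,
              short_sdlog = short_sdlog,
              cons_levels = cons_levels, cons_block_mean = cons_block_mean,
              cons_noise_rate = cons_noise_rate, flank_cons = flank_cons,
              exon_coupling = exon_coupling, tau_expr = tau_expr,
              tissues = tissues, marks = marks,
              flank_peak_scale = flank_peak_scale,
              repeat_density = repeat_density,
              repeat_mean_len = repeat_mean_len,
              intergenic = as.integer(intergenic),
              n_overlap_genes = as.integer(n_overlap_genes),
              trim = as.integer(trim))
  stopifnot(n_genes >= 1, all(cons_levels >= 0), all(cons_levels <= 1),
            all(marks$background > 0), all(marks$background < 1),
            repeat_density >= 0, repeat_density < 1,
            abs(tau_expr) < 1, short_first_prob >= 0, short_first_prob <= 1)
  if (exp(min(intron_meanlog)) <= 2 * cfg$trim)
    stop("infeasible config: expected intron length <= 2 * trim")
  structure(cfg, class = "sim_config")
}

# integer block process over [s, e]: alternating exponential gaps/blocks
# with expected covered fraction p and mean block length bmean
gen_blocks <- function(s, e, p, bmean) {
  L <- e - s + 1L
  if (L < 3L || p <= 0) return(NULL)
  gmean <- bmean * (1 - p) / p
  m <- max(8L, ceiling(2 * L / (bmean + gmean)) + 4L)
  gaps <- pmax(1, round(stats::rexp(m, 1 / gmean)))
  blocks <- pmax(1, round(stats::rexp(m, 1 / bmean)))
  while (sum(gaps + blocks) < L) {
    gaps <- c(gaps, pmax(1, round(stats::rexp(m, 1 / gmean))))
    blocks <- c(blocks, pmax(1, round(stats::rexp(m, 1 / bmean))))
  }
  tot <- cumsum(gaps + blocks)
  bs <- s + tot - blocks
  be <- s + tot - 1
  keep <- bs <= e
  if (!any(keep)) return(NULL)
  cbind(start = bs[keep], end = pmin(be[keep], e))
}

blocks_to_gr <- function(chrom, mat_list) {
  mat <- do.call(rbind, mat_list)
  if (is.null(mat) || nrow(mat) == 0L) return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(chrom, IRanges::IRanges(mat[, 1L], mat[, 2L]))
}

# overlap of [s,e] with a block matrix, in bases
blocks_overlap <- function(mat, s, e) {
  if (is.null(mat)) return(0L)
  sum(pmax(0L, pmin(mat[, 2L], e) - pmax(mat[, 1L], s) + 1L))
}

# width-based Poisson peak placement inside a region set, clipped to it
place_peaks <- function(regions, rate, wmean, chrom) {
  if (length(regions) == 0L || rate <= 0) return(GenomicRanges::GRanges())
  w <- GenomicRanges::width(regions)
  n <- stats::rpois(length(regions), w * rate / wmean)
  if (sum(n) == 0L) return(GenomicRanges::GRanges())
  idx <- rep(seq_along(regions), n)
  rs <- GenomicRanges::start(regions)[idx]
  re <- GenomicRanges::end(regions)[idx]
  ps <- rs + floor(stats::runif(sum(n)) * w[idx])
  pw <- pmax(20, round(stats::rlnorm(sum(n), log(wmean), 0.3)))
  GenomicRanges::GRanges(chrom, IRanges::IRanges(ps, pmin(ps + pw - 1, re)))
}

#' Simulate a synthetic cohort with planted effects
#'
#' @param cfg A [sim_config()].
#' @return A `sim_cohort` list: `transcripts` (named list of
#'   `transcript_model`s), `track` (conservation `GRanges`), `mask`,
#'   `peaks` (named list per mark), `expression` (data.frame), `truth`
#'   (planted and realized parameters) and `cfg`.
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  ng <- cfg$n_genes
  mk <- cfg$marks

  ## gene structures ------------------------------------------------------
  n_ex <- 2L + stats::rnbinom(ng, size = cfg$exon_count_size,
                              mu = cfg$exon_count_mu - 2)
  n_ex <- pmin(pmax(n_ex, cfg$exon_count_range[1L]), cfg$exon_count_range[2L])
  short1 <- stats::runif(ng) < cfg$short_first_prob
  strands <- sample(c("+", "-"), ng, replace = TRUE)
  c1_target <- pmin(pmax(cfg$cons_levels[1L] *
                           (1 + cfg$exon_coupling * (n_ex - mean(n_ex))),
                         0.005), 0.6)

  transcripts <- vector("list", ng)
  gene_ids <- sprintf("G%05d", seq_len(ng))
  cursor <- 10000L
  for (i in seq_len(ng)) {
    ne <- n_ex[i]
    el <- pmin(pmax(round(stats::rlnorm(ne, cfg$exon_meanlog, cfg$exon_sdlog)),
                    30), 3000)
    el[1L] <- if (short1[i]) {
      min(max(round(stats::rlnorm(1, cfg$short_exon1_meanlog, cfg$short_sdlog)),
              30), 3000)
    } else {
      min(max(round(stats::rlnorm(1, cfg$exon1_meanlog, cfg$exon1_sdlog)),
              30), 3000)
    }
    ml <- cfg$intron_meanlog[pmin(seq_len(ne - 1L), 4L)]
    il <- pmin(pmax(round(stats::rlnorm(ne - 1L, ml, cfg$intron_sdlog)),
                    80), 60000)
    if (short1[i]) {
      il[1L] <- min(max(round(stats::rlnorm(1, cfg$short_intron1_meanlog,
                                            cfg$short_sdlog)), 80), 60000)
      if (ne >= 2L)
        el[2L] <- min(max(round(stats::rlnorm(1, log(150), 0.3)), 30), 3000)
    }
    lens <- integer(2L * ne - 1L)
    lens[seq(1L, 2L * ne - 1L, by = 2L)] <- el
    if (ne > 1L) lens[seq(2L, 2L * ne - 2L, by = 2L)] <- il
    if (strands[i] == "-") lens <- rev(lens)
    starts <- cursor + c(0L, cumsum(lens[-length(lens)]))
    ends <- starts + lens - 1L
    exi <- seq(1L, length(lens), by = 2L)
    transcripts[[i]] <- transcript_model(paste0(gene_ids[i], ".1"),
                                         gene_ids[i], cfg$chrom, strands[i],
                                         starts[exi], ends[exi])
    gap <- 4500L + round(stats::rexp(1, 1 / cfg$intergenic))
    cursor <- ends[length(ends)] + gap
  }

  ## planted overlap genes (nested in host first introns) -----------------
  introns <- extract_introns(transcripts)
  if (cfg$n_overlap_genes > 0L) {
    fi <- introns[introns$ordinal == 1L, , drop = FALSE]
    hosts <- fi[fi$raw_length >= 3000L, , drop = FALSE]
    nov <- min(cfg$n_overlap_genes, nrow(hosts))
    hosts <- hosts[sample.int(nrow(hosts), nov), , drop = FALSE]
    for (j in seq_len(nov)) {
      mid <- (hosts$start[j] + hosts$end[j]) %/% 2L
      gid <- sprintf("GOVL%03d", j)
      transcripts[[length(transcripts) + 1L]] <-
        transcript_model(paste0(gid, ".1"), gid, cfg$chrom, "+",
                         c(mid, mid + 600L), c(mid + 199L, mid + 799L))
    }
    introns <- extract_introns(transcripts)
  }
  names(transcripts) <- vapply(transcripts, function(t) t$transcript_id,
                               character(1))

  ## conservation track ---------------------------------------------------
  primary <- introns$gene_id %in% gene_ids
  ord_all <- introns$ordinal
  gidx <- match(introns$gene_id, gene_ids)
  targets <- ifelse(ord_all == 1L, c1_target[gidx],
                    cfg$cons_levels[pmin(ord_all, 4L)])
  intron_blocks <- vector("list", nrow(introns))
  realized <- rep(NA_real_, nrow(introns))
  for (r in which(primary)) {
    b <- gen_blocks(introns$start[r], introns$end[r], targets[r],
                    cfg$cons_block_mean)
    intron_blocks[[r]] <- b
    ts <- introns$start[r] + cfg$trim
    te <- introns$end[r] - cfg$trim
    if (te - ts + 1L >= 50L)
      realized[r] <- blocks_overlap(b, ts, te) / (te - ts + 1L)
  }
  cons_gr <- blocks_to_gr(cfg$chrom, intron_blocks)

  flank_blocks <- lapply(seq_len(ng), function(i) {
    fr <- flank_regions(transcripts[[i]],
                        filter_config(flank_length = 2000L))
    up <- fr[names(fr) == "upstream"]
    if (length(up) == 0L) return(NULL)
    gen_blocks(GenomicRanges::start(up), GenomicRanges::end(up),
               cfg$flank_cons, cfg$cons_block_mean)
  })
  flank_gr <- GenomicRanges::setdiff(blocks_to_gr(cfg$chrom, flank_blocks),
                                     cons_gr)
  noise_raw <- lapply(which(primary), function(r) {
    gen_blocks(introns$start[r], introns$end[r], cfg$cons_noise_rate,
               cfg$cons_block_mean)
  })
  noise_gr <- GenomicRanges::setdiff(blocks_to_gr(cfg$chrom, noise_raw),
                                     GenomicRanges::reduce(c(cons_gr, flank_gr)))
  hi <- c(cons_gr, flank_gr)
  S4Vectors::mcols(hi)$score <- round(stats::runif(length(hi), 0.55, 0.98), 3)
  S4Vectors::mcols(noise_gr)$score <- round(stats::runif(length(noise_gr),
                                                         0.05, 0.45), 3)
  track <- GenomicRanges::sort(c(hi, noise_gr), ignore.strand = TRUE)

  ## repeat mask ----------------------------------------------------------
  chrom_end <- max(vapply(transcripts, function(t) max(t$exon_end),
                          integer(1))) + 10000L
  nrep <- stats::rpois(1, chrom_end * cfg$repeat_density / cfg$repeat_mean_len)
  if (nrep > 0L) {
    rs <- 1L + floor(stats::runif(nrep) * (chrom_end - 1L))
    rw <- pmax(30, round(stats::rexp(nrep, 1 / cfg$repeat_mean_len)))
    mask <- GenomicRanges::reduce(GenomicRanges::GRanges(
      cfg$chrom, IRanges::IRanges(rs, pmin(rs + rw - 1L, chrom_end))))
  } else {
    mask <- GenomicRanges::GRanges()
  }

  ## peaks ----------------------------------------------------------------
  fi_rows <- which(introns$ordinal == 1L & primary)
  ts <- introns$start[fi_rows] + cfg$trim
  te <- introns$end[fi_rows] - cfg$trim
  use <- te - ts + 1L >= 50L
  fi_rows <- fi_rows[use]; ts <- ts[use]; te <- te[use]
  spanw <- te - ts + 1L
  B <- sum(spanw)
  off0 <- c(0L, cumsum(spanw))[seq_along(spanw)]
  ind <- logical(B)
  for (j in seq_along(fi_rows)) {
    b <- intron_blocks[[fi_rows[j]]]
    if (is.null(b)) next
    cs <- pmax(b[, 1L], ts[j]); ce <- pmin(b[, 2L], te[j])
    keep <- cs <= ce
    if (!any(keep)) next
    ind[sequence(ce[keep] - cs[keep] + 1L,
                 from = off0[j] + cs[keep] - ts[j] + 1L)] <- TRUE
  }

  spans_gr <- GenomicRanges::GRanges(cfg$chrom, IRanges::IRanges(ts, te))
  gene_spans <- GenomicRanges::reduce(GenomicRanges::GRanges(
    cfg$chrom,
    IRanges::IRanges(vapply(transcripts, function(t) min(t$exon_start), integer(1)),
                     vapply(transcripts, function(t) max(t$exon_end), integer(1)))))
  first_ex <- GenomicRanges::GRanges(cfg$chrom, IRanges::IRanges(
    vapply(transcripts, function(t)
      if (t$strand == "+") t$exon_start[1L] else t$exon_start[n_exons(t)],
      integer(1)),
    vapply(transcripts, function(t)
      if (t$strand == "+") t$exon_end[1L] else t$exon_end[n_exons(t)],
      integer(1))))
  flanks_all <- do.call(c, unname(lapply(transcripts, flank_regions,
                                         cfg = filter_config())))
  regA <- GenomicRanges::setdiff(gene_spans,
                                 GenomicRanges::reduce(c(spans_gr, first_ex)))
  regB <- GenomicRanges::reduce(c(nostrand(flanks_all), first_ex))

  peaks <- list()
  for (m in seq_len(nrow(mk))) {
    p0 <- mk$background[m]
    p1 <- stats::plogis(stats::qlogis(p0) + mk$log_odds[m])
    pv <- rep(p0, B)
    pv[ind] <- p1
    covered <- stats::runif(B) < pv
    acc_s <- vector("list", length(fi_rows))
    acc_e <- vector("list", length(fi_rows))
    for (j in seq_along(fi_rows)) {
      v <- covered[(off0[j] + 1L):(off0[j] + spanw[j])]
      r <- rle(v)
      ce <- cumsum(r$lengths)
      cs <- ce - r$lengths + 1L
      sel <- r$values
      acc_s[[j]] <- ts[j] + cs[sel] - 1L
      acc_e[[j]] <- ts[j] + ce[sel] - 1L
    }
    base_gr <- GenomicRanges::GRanges(
      cfg$chrom, IRanges::IRanges(unlist(acc_s), unlist(acc_e)))
    bgA <- place_peaks(regA, p0, mk$width[m], cfg$chrom)
    bgB <- place_peaks(regB, p0 * cfg$flank_peak_scale, mk$width[m], cfg$chrom)
    peaks[[mk$mark[m]]] <- GenomicRanges::reduce(c(base_gr, bgA, bgB))
  }

  ## expression -----------------------------------------------------------
  realized_c1 <- rep(NA_real_, ng)
  fi_all <- which(introns$ordinal == 1L & primary)
  realized_c1[match(introns$gene_id[fi_all], gene_ids)] <- realized[fi_all]
  ok <- !is.na(realized_c1)
  rho <- sin(pi * cfg$tau_expr / 2)
  zc <- stats::qnorm(rank(realized_c1[ok], ties.method = "average") /
                       (sum(ok) + 1))
  all_ids <- vapply(transcripts, function(t) t$gene_id, character(1))
  all_ids <- unique(all_ids)
  expr <- data.frame(gene_id = all_ids, stringsAsFactors = FALSE)
  for (tis in cfg$tissues) {
    z <- stats::rnorm(length(all_ids))
    z[match(gene_ids[ok], all_ids)] <-
      rho * zc + sqrt(1 - rho^2) * stats::rnorm(sum(ok))
    expr[[tis]] <- round(pmax(0, 3 + 1.5 * z), 4)
  }

  ## truth ----------------------------------------------------------------
  ord_means <- tapply(realized[primary & !is.na(realized)],
                      pmin(ord_all[primary & !is.na(realized)], 10L), mean)
  truth <- list(
    planted = list(cons_levels = cfg$cons_levels,
                   exon_coupling = cfg$exon_coupling,
                   tau_expr = cfg$tau_expr,
                   mark_log_odds = stats::setNames(mk$log_odds, mk$mark),
                   mark_background = stats::setNames(mk$background, mk$mark),
                   null = cfg$null),
    genes = data.frame(gene_id = gene_ids, n_exons = n_ex,
                       strand = strands, short_first = short1,
                       target_c1 = c1_target, realized_c1 = realized_c1,
                       stringsAsFactors = FALSE),
    realized = list(
      mean_c_by_ordinal = as.list(ord_means),
      tau_exons = if (sum(ok) > 2L)
        stats::cor(n_ex[ok], realized_c1[ok], method = "kendall")
      else NA_real_),
    spiked = character(0))

  structure(list(transcripts = transcripts, track = track, mask = mask,
                 peaks = peaks, expression = expr, truth = truth, cfg = cfg),
            class = "sim_cohort")
}

#' Spike promoter spillover into chosen genes
#'
#' For each chosen gene and mark, adds one peak covering the entire
#' upstream flank and first exon and extending into the 5' end of the
#' first intron, so the spillover filter must exclude the gene.
#'
#' @param sim A `sim_cohort`.
#' @param gene_ids Genes to spike (empty vector leaves the bundle
#'   untouched).
#' @param marks Marks to spike; default all.
#' @return The modified `sim_cohort`; spiked ids recorded in
#'   `truth$spiked`.
#' @export
spike_spillover <- function(sim, gene_ids, marks = names(sim$peaks)) {
  if (length(gene_ids) == 0L) return(sim)
  flank <- 2000L
  for (g in gene_ids) {
    t <- sim$transcripts[[paste0(g, ".1")]]
    if (is.null(t)) stop("unknown gene: ", g)
    introns <- extract_introns(t)
    i1 <- introns[introns$ordinal == 1L, , drop = FALSE]
    if (nrow(i1) == 0L) stop("gene has no intron: ", g)
    spill <- min(1000L, i1$raw_length %/% 3L)
    if (t$strand == "+") {
      s <- max(1L, min(t$exon_start) - flank)
      e <- i1$start + spill - 1L
    } else {
      s <- i1$end - spill + 1L
      e <- max(t$exon_end) + flank
    }
    pk <- GenomicRanges::GRanges(t$chrom, IRanges::IRanges(s, e))
    for (m in marks) {
      sim$peaks[[m]] <- GenomicRanges::reduce(c(sim$peaks[[m]], pk))
    }
  }
  sim$truth$spiked <- sort(unique(c(sim$truth$spiked, gene_ids)))
  sim
}

#' Write a simulated cohort as an input bundle
#'
#' Emits `genes.gtf`, `conservation.bedGraph`, `mask.bed`,
#' `peaks_<MARK>.bed`, `expression.tsv` and `truth.json` into `dir`, all in
#' the same formats the pipeline's readers consume, so synthetic and real
#' input are indistinguishable downstream.
#'
#' @param sim A `sim_cohort`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_bundle <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_gtf(sim$transcripts, file.path(dir, "genes.gtf"))
  write_bedgraph(sim$track, file.path(dir, "conservation.bedGraph"))
  write_bed6(sim$mask, file.path(dir, "mask.bed"))
  for (m in names(sim$peaks)) {
    write_bed6(sim$peaks[[m]], file.path(dir, sprintf("peaks_%s.bed", m)))
  }
  utils::write.table(sim$expression, file.path(dir, "expression.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}

#' Read an input bundle from disk
#'
#' @param dir Directory produced by [write_bundle()] (or hand-assembled in
#'   the same layout).
#' @return A list with `transcripts`, `track`, `mask`, `peaks`,
#'   `expression` and (when present) `truth`.
#' @export
read_bundle <- function(dir) {
  pk_files <- list.files(dir, pattern = "^peaks_.*\\.bed$", full.names = TRUE)
  marks <- sub("^peaks_(.*)\\.bed$", "\\1", basename(pk_files))
  peaks <- lapply(seq_along(pk_files), function(i)
    read_peaks(pk_files[i], mark = marks[i]))
  names(peaks) <- marks
  truth_path <- file.path(dir, "truth.json")
  list(transcripts = read_gene_models(file.path(dir, "genes.gtf")),
       track = read_score_track(file.path(dir, "conservation.bedGraph")),
       mask = read_mask(file.path(dir, "mask.bed")),
       peaks = peaks,
       expression = read_expression(file.path(dir, "expression.tsv")),
       truth = if (file.exists(truth_path))
         jsonlite::read_json(truth_path, simplifyVector = TRUE) else NULL)
}

#' Simulate and write a bundle in one step
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory.
#' @return The `sim_cohort`, invisibly.
#' @export
simulate_bundle <- function(cfg, dir) {
  sim <- simulate_cohort(cfg)
  write_bundle(sim, dir)
  invisible(sim)
}
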