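# Brute-force oracles and coordinate helpers. Oracles operate base-by-base
# or pair-by-pair and share no code with the interval/statistics paths they
# check. Test fixtures are written in 0-based half-open coordinates [s, e)
# and converted here, so they can be read off interval sketches directly.

gr0 <- function(start0, end0, chrom = "chr1", strand = "*") {
  if (length(start0) == 0L) return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1, end0),
                         strand = strand)
}

track0 <- function(start0, end0, score, chrom = "chr1") {
  gr <- gr0(start0, end0, chrom)
  S4Vectors::mcols(gr)$score <- score
  gr
}

# all 1-based base positions of a (single-chromosome) region set
bases_of <- function(gr) {
  if (length(gr) == 0L) return(integer(0))
  sort(unique(unlist(mapply(seq.int, GenomicRanges::start(gr),
                            GenomicRanges::end(gr), SIMPLIFY = FALSE))))
}

# per-base score lookup (0 where the track is silent)
base_scores <- function(positions, track) {
  sc <- numeric(length(positions))
  for (i in seq_along(track)) {
    hit <- positions >= GenomicRanges::start(track)[i] &
      positions <= GenomicRanges::end(track)[i]
    sc[hit] <- S4Vectors::mcols(track)$score[i]
  }
  sc
}

bf_conserved_fraction <- function(regions, track, threshold) {
  pos <- bases_of(regions)
  if (length(pos) == 0L) return(NA_real_)
  mean(base_scores(pos, track) >= threshold)
}

bf_coverage_fraction <- function(regions, peaks) {
  pos <- bases_of(regions)
  if (length(pos) == 0L) return(NA_real_)
  mean(pos %in% bases_of(peaks))
}

bf_partition_bases <- function(regions, track, threshold) {
  pos <- bases_of(regions)
  cons <- base_scores(pos, track) >= threshold
  list(conserved = pos[cons], nonconserved = pos[!cons])
}

bf_build_table <- function(regions, track, peaks, threshold) {
  p <- bf_partition_bases(regions, track, threshold)
  pk <- bases_of(peaks)
  c(SC = sum(p$conserved %in% pk),
    NC = sum(!(p$conserved %in% pk)),
    SN = sum(p$nonconserved %in% pk),
    NN = sum(!(p$nonconserved %in% pk)))
}

# Kendall tau-b by full pair enumeration
bf_tau_b <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      s <- sign(x[j] - x[i]) * sign(y[j] - y[i])
      if (s > 0) conc <- conc + 1 else if (s < 0) disc <- disc + 1
      if (x[i] == x[j]) tx <- tx + 1
      if (y[i] == y[j]) ty <- ty + 1
    }
  }
  n0 <- choose(n, 2)
  (conc - disc) / sqrt((n0 - tx) * (n0 - ty))
}

# one-sided (a shifted up) exact rank-sum p by enumerating all assignments
# of the pooled ranks to group a; valid for tie-free pooled samples
bf_wilcox_greater <- function(a, b) {
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  wobs <- sum(r[seq_along(a)])
  combs <- utils::combn(length(pooled), length(a))
  mean(apply(combs, 2, function(idx) sum(r[idx])) >= wobs)
}

# random small instance for the interval oracles
random_instance <- function() {
  nreg <- sample(1:3, 1)
  rs <- sort(sample(0:280, 2 * nreg))
  regions <- gr0(rs[seq(1, 2 * nreg, 2)], rs[seq(2, 2 * nreg, 2)])
  nt <- sample(0:6, 1)
  track <- if (nt > 0) {
    ts <- sort(sample(0:290, 2 * nt))
    track0(ts[seq(1, 2 * nt, 2)], ts[seq(2, 2 * nt, 2)],
           round(stats::runif(nt), 3))
  } else track0(integer(0), integer(0), numeric(0))
  np <- sample(0:5, 1)
  peaks <- if (np > 0) {
    ps <- sort(sample(0:300, 2 * np))
    gr0(ps[seq(1, 2 * np, 2)], ps[seq(2, 2 * np, 2)])
  } else GenomicRanges::GRanges()
  list(regions = regions, track = track, peaks = peaks,
       threshold = sample(c(0.3, 0.5, 0.7), 1))
}
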