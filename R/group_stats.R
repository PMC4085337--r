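## Cohort-level statistics: ordinal group comparisons, binned Kendall
## correlations, exon-count-group regressions, expression correlations.

#' Kendall tau-b rank correlation with normal-approximation p-value
#'
#' Thin wrapper over [stats::cor.test()] (`method = "kendall"`,
#' `exact = FALSE`): tau-b handles ties in either variable, and the p-value
#' uses the tie-corrected normal approximation. Degenerate inputs (fewer
#' than two pairs, or a constant variable) return `NA` sentinels.
#'
#' @param x,y Numeric vectors of equal length.
#' @return A list with `tau`, `p_value`, `n`.
#' @export
kendall_tau <- function(x, y) {
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 2L || length(unique(x)) < 2L || length(unique(y)) < 2L) {
    return(list(tau = NA_real_, p_value = NA_real_, n = n))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "kendall",
                                         exact = FALSE))
  list(tau = unname(ct$estimate), p_value = ct$p.value, n = n)
}

#' Group per-region fractions by intron ordinal
#'
#' @param ordinal Integer vector of intron ordinals.
#' @param value Parallel vector of fractions (conserved or coverage).
#' @param max_ordinal Ordinals above this are dropped (sparse groups).
#' @return An `ordinal_group_table`: list with `values` (fractions split by
#'   ordinal) and `table` (per-group n, median, quartiles).
#' @export
ordinal_summary <- function(ordinal, value, max_ordinal = 20L) {
  keep <- !is.na(value) & ordinal <= max_ordinal
  ordinal <- ordinal[keep]; value <- value[keep]
  ords <- sort(unique(ordinal))
  values <- split(value, factor(ordinal, levels = ords))
  tab <- data.frame(
    ordinal = ords,
    n = vapply(values, length, integer(1)),
    q1 = vapply(values, function(v) unname(stats::quantile(v, 0.25)), numeric(1)),
    median = vapply(values, stats::median, numeric(1)),
    q3 = vapply(values, function(v) unname(stats::quantile(v, 0.75)), numeric(1)),
    row.names = NULL)
  structure(list(values = values, table = tab), class = "ordinal_group_table")
}

rank_sum_p <- function(a, b, alternative) {
  if (length(unique(c(a, b))) == 1L) return(1)  # all ties: no evidence
  exact <- length(a) <= 10L && length(b) <= 10L
  suppressWarnings(
    stats::wilcox.test(a, b, alternative = alternative, exact = exact)$p.value)
}

#' Rank-sum tests of the first ordinal group against the rest
#'
#' Compares group 1 to every other ordinal group separately and to all
#' other groups pooled (Mann-Whitney / Wilcoxon rank-sum). Exact
#' enumeration is used when both sides have at most 10 observations and no
#' ties; otherwise the tie-corrected normal approximation.
#'
#' @param tab An [ordinal_summary()] result.
#' @param alternative `"greater"` (group 1 shifted up) or `"two.sided"`.
#' @return A data.frame with one row per comparison (`"pooled"` first,
#'   then `"ord<k>"`), group sizes, medians and the p-value.
#' @export
first_vs_rest_test <- function(tab, alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  v <- tab$values
  stopifnot("1" %in% names(v), length(v) >= 2L)
  g1 <- v[["1"]]
  others <- v[names(v) != "1"]
  pooled <- unlist(others, use.names = FALSE)
  rows <- list(data.frame(comparison = "pooled",
                          n1 = length(g1), n2 = length(pooled),
                          median1 = stats::median(g1),
                          median2 = stats::median(pooled),
                          p_value = rank_sum_p(g1, pooled, alternative)))
  for (k in names(others)) {
    rows[[length(rows) + 1L]] <- data.frame(
      comparison = paste0("ord", k),
      n1 = length(g1), n2 = length(others[[k]]),
      median1 = stats::median(g1), median2 = stats::median(others[[k]]),
      p_value = rank_sum_p(g1, others[[k]], alternative))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Binned Kendall correlation between two per-gene quantities
#'
#' Pairs are optionally cleared of double zeros (regions carrying neither
#' conservation nor signal), sorted by `x`, and aggregated into consecutive
#' bins of exactly `bin_size` items (an incomplete trailing bin is
#' dropped). Kendall tau-b with tie correction is computed both on the
#' binned means and on the raw (unbinned) pairs.
#'
#' @param x,y Numeric vectors of equal length (`x` is the binning variable).
#' @param bin_size Number of items per bin.
#' @param drop_zero_zero Drop pairs where both values are exactly 0.
#' @return A list: `series` (data.frame of bin means), `bin_size`, `n_used`,
#'   `n_leftover` (items in the dropped trailing bin), `n_dropped_zero`,
#'   `binned` and `raw` ([kendall_tau()] results; `binned` is an `NA`
#'   sentinel when fewer than two complete bins exist).
#' @export
binned_kendall <- function(x, y, bin_size, drop_zero_zero = TRUE) {
  stopifnot(length(x) == length(y), bin_size >= 1L)
  keep <- !(is.na(x) | is.na(y))
  n_dropped_zero <- 0L
  if (drop_zero_zero) {
    zz <- keep & x == 0 & y == 0
    n_dropped_zero <- sum(zz)
    keep <- keep & !zz
  }
  x <- x[keep]; y <- y[keep]
  o <- order(x)
  xs <- x[o]; ys <- y[o]
  n <- length(xs)
  nb <- n %/% bin_size
  n_leftover <- n - nb * bin_size
  if (nb >= 1L) {
    idx <- rep(seq_len(nb), each = bin_size)
    used <- seq_len(nb * bin_size)
    mx <- as.numeric(tapply(xs[used], idx, mean))
    my <- as.numeric(tapply(ys[used], idx, mean))
  } else {
    mx <- my <- numeric(0)
  }
  binned <- if (nb >= 2L) kendall_tau(mx, my) else
    list(tau = NA_real_, p_value = NA_real_, n = nb)
  list(series = data.frame(mean_x = mx, mean_y = my),
       bin_size = as.integer(bin_size), n_used = n,
       n_leftover = as.integer(n_leftover),
       n_dropped_zero = as.integer(n_dropped_zero),
       binned = binned, raw = kendall_tau(xs, ys))
}

#' Regression of group-mean values on exon count
#'
#' Genes are grouped by exon count: G1 holds genes with two exons, up to
#' G`max_group` with `max_group + 1` exons (genes beyond that are
#' excluded). Each group's mean value is regressed on the exon count by
#' ordinary least squares, so the slope is in per-exon units.
#'
#' @param n_exons Integer vector of per-gene exon counts (>= 2).
#' @param value Parallel vector of per-gene values (e.g. first-intron
#'   conserved fraction).
#' @param max_group Highest group index; default 20 (i.e. 21 exons).
#' @return A list with `slope`, `intercept`, `r_squared`, `n_groups` and a
#'   `groups` data.frame; `NA` sentinels when fewer than two non-empty
#'   groups exist.
#' @export
exon_group_regression <- function(n_exons, value, max_group = 20L) {
  keep <- !is.na(value) & n_exons >= 2L & n_exons <= max_group + 1L
  n_exons <- n_exons[keep]; value <- value[keep]
  counts <- sort(unique(n_exons))
  if (length(counts) < 2L) {
    return(list(slope = NA_real_, intercept = NA_real_,
                r_squared = NA_real_, n_groups = length(counts),
                groups = NULL))
  }
  mv <- as.numeric(tapply(value, factor(n_exons, levels = counts), mean))
  groups <- data.frame(exon_count = counts,
                       group = paste0("G", counts - 1L),
                       n = as.integer(table(factor(n_exons, levels = counts))),
                       mean_value = mv)
  if (stats::var(mv) == 0) {
    return(list(slope = 0, intercept = mv[1L], r_squared = 0,
                n_groups = length(counts), groups = groups))
  }
  fit <- stats::lm(mv ~ counts)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((mv - mean(mv))^2)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = r2,
       n_groups = length(counts), groups = groups)
}

#' Correlation between gene expression and first-intron conservation
#'
#' Intersects the two named vectors on shared gene ids and delegates to
#' [binned_kendall()] with expression as the binning variable.
#'
#' @param cons Named vector of per-gene conserved fractions.
#' @param expr Named vector of per-gene expression values
#'   (log2(RPKM + 1) scale).
#' @param bin_size Genes per bin; default 50.
#' @param drop_zero_zero Passed through to [binned_kendall()].
#' @return A [binned_kendall()] result (`NA` sentinels on an empty
#'   intersection).
#' @export
expression_correlation <- function(cons, expr, bin_size = 50L,
                                   drop_zero_zero = TRUE) {
  ids <- intersect(names(cons), names(expr))
  binned_kendall(unname(expr[ids]), unname(cons[ids]),
                 bin_size = bin_size, drop_zero_zero = drop_zero_zero)
}
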