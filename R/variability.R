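# Repeat dynamic index (RDI): trimmed population SD of per-sample ERCs,
# rank-normalized to nRDI and binned into five variability tiers.

TIER_LEVELS <- c("vlSTR", "lSTR", "mSTR", "hSTR", "vhSTR")

# Nearest-rank percentile indices on the ascending sort of n values.
# Lower index: ceiling(q*n), floored at 1. Upper index: ceiling(q*n), but
# when q*n is not an integer the index is capped at n-1 so that a lone
# maximum outlier is excluded rather than becoming the bound itself.
# Near-integer products are snapped to the integer to dodge binary-fraction
# artifacts (0.95*20 must be 19, 0.05*20 must be 1).
trim_indices <- function(n, lower, upper) {
  snap <- function(x) if (abs(x - round(x)) < 1e-9) round(x) else x
  lo <- snap(lower * n)
  hi <- snap(upper * n)
  i_lo <- max(1L, as.integer(ceiling(lo)))
  i_hi <- as.integer(ceiling(hi))
  if (hi != round(hi)) i_hi <- min(i_hi, n - 1L)
  i_hi <- max(i_hi, i_lo)
  c(i_lo, i_hi)
}

#' Trim repeat counts to the percentile-bounded normal range
#'
#' Computes nearest-rank 5th/95th percentile bounds and keeps every value
#' inside `[p5, p95]` (inclusive: trimming is value-based, so ties at the
#' bounds are retained). This removes minimum/maximum outlier genotypes
#' before dispersion is measured.
#'
#' @param ercs integer vector of per-sample ERCs (>= 2 values).
#' @param lower,upper trim quantiles (defaults 0.05 / 0.95).
#' @return `list(kept =, p5 =, p95 =)`; `kept` preserves input order.
#' @export
#' @examples
#' trim_counts(1:20)  # p5 = 1, p95 = 19, the value 20 is removed
trim_counts <- function(ercs, lower = 0.05, upper = 0.95) {
  ercs <- ercs[!is.na(ercs)]
  n <- length(ercs)
  if (n < 2L) stop("need at least 2 non-missing values", call. = FALSE)
  stopifnot(lower > 0, upper < 1, lower < upper)
  s <- sort(ercs)
  idx <- trim_indices(n, lower, upper)
  p5 <- s[idx[1L]]; p95 <- s[idx[2L]]
  list(kept = ercs[ercs >= p5 & ercs <= p95], p5 = p5, p95 = p95)
}

#' Repeat dynamic index of a trimmed ERC vector
#'
#' The population standard deviation `sqrt(sum((R - Rbar)^2) / N)` over the
#' retained repeat counts (divisor `N`, not `N - 1`).
#'
#' @param kept numeric vector of retained ERCs (non-empty).
#' @return Non-negative numeric RDI.
#' @export
#' @examples
#' compute_rdi(c(10, 10, 12, 12))  # 1
compute_rdi <- function(kept) {
  kept <- kept[!is.na(kept)]
  if (length(kept) == 0L) stop("no values to score", call. = FALSE)
  m <- mean(kept)
  sqrt(sum((kept - m)^2) / length(kept))
}

#' Rank-normalize RDI scores to nRDI in [0, 1]
#'
#' nRDI = (rank - 1) / (L - 1), with ascending midranks (ties share their
#' average rank); the minimum RDI maps to 0 and the maximum to 1.
#'
#' @param rdi named numeric vector of per-locus RDI scores (>= 2 loci).
#' @return Named numeric vector of nRDI values in `[0, 1]`.
#' @export
normalize_rdi <- function(rdi) {
  L <- length(rdi)
  if (L < 2L) stop("rank normalization needs at least 2 loci", call. = FALSE)
  if (anyNA(rdi)) stop("rdi contains NA", call. = FALSE)
  (rank(rdi, ties.method = "average") - 1) / (L - 1)
}

#' Classify nRDI into the five variability tiers
#'
#' Bins `[0, 0.2)`, `[0.2, 0.4)`, `[0.4, 0.6)`, `[0.6, 0.8)`, `[0.8, 1]`
#' map to `vlSTR`, `lSTR`, `mSTR`, `hSTR`, `vhSTR` (internal boundaries
#' left-closed; 1.0 belongs to `vhSTR`).
#'
#' @param nrdi numeric vector in `[0, 1]`.
#' @return Factor with levels `vlSTR < lSTR < mSTR < hSTR < vhSTR`.
#' @export
classify_tier <- function(nrdi) {
  ok <- !is.na(nrdi)
  if (any(nrdi[ok] < 0 | nrdi[ok] > 1)) {
    stop("nrdi values must lie in [0, 1]", call. = FALSE)
  }
  idx <- findInterval(nrdi, c(0, 0.2, 0.4, 0.6, 0.8))
  factor(TIER_LEVELS[idx], levels = TIER_LEVELS, ordered = TRUE)
}

#' Score per-locus variability over a genotype matrix
#'
#' For each locus with non-missing ERCs in at least `min_fraction` of the
#' cohort (and at least 2 samples): trim to the `[p5, p95]` normal range,
#' compute RDI; then rank-normalize RDI across all scored loci to nRDI and
#' assign tiers. Unscored loci are retained with `NA` statistics.
#'
#' @param gmat genotype matrix from [build_genotype_matrix()].
#' @param min_fraction minimum fraction of cohort samples with a genotype
#'   for a locus to be scored (default 0.8).
#' @param lower,upper trim quantiles (defaults 0.05 / 0.95).
#' @return data.table with one row per locus: `locus_id`, `n_total`,
#'   `n_used`, `mean_trimmed`, `p5`, `p95`, `rdi`, `nrdi`, `tier`.
#' @export
score_variability <- function(gmat, min_fraction = 0.8,
                              lower = 0.05, upper = 0.95) {
  n_samples <- ncol(gmat)
  loci <- rownames(gmat)
  res <- data.table::data.table(
    locus_id = loci,
    n_total = as.integer(rowSums(!is.na(gmat))),
    n_used = NA_integer_, mean_trimmed = NA_real_,
    p5 = NA_integer_, p95 = NA_integer_,
    rdi = NA_real_, nrdi = NA_real_
  )
  scorable <- res$n_total >= 2L &
    res$n_total >= min_fraction * n_samples
  for (i in which(scorable)) {
    tr <- trim_counts(gmat[i, ], lower = lower, upper = upper)
    res$n_used[i] <- length(tr$kept)
    res$mean_trimmed[i] <- mean(tr$kept)
    res$p5[i] <- as.integer(tr$p5)
    res$p95[i] <- as.integer(tr$p95)
    res$rdi[i] <- compute_rdi(tr$kept)
  }
  if (sum(scorable) >= 2L) {
    res$nrdi[scorable] <- normalize_rdi(res$rdi[scorable])
  }
  res$tier <- classify_tier(res$nrdi)
  res[]
}

#' Decile distribution of a locus subset over the nRDI scale
#'
#' Proportion of subset loci whose nRDI falls in each of the ten bins
#' `[0, 0.1)`, ..., `[0.9, 1]`. On the full scored set this is uniform by
#' construction of the rank normalization; deviation from 0.1 per bin is
#' the subset's variability signature.
#'
#' @param records variability table from [score_variability()].
#' @param subset character vector of locus ids (default: all scored loci).
#' @return Numeric vector of 10 proportions summing to 1.
#' @export
decile_distribution <- function(records, subset = NULL) {
  scored <- records[!is.na(records$nrdi), ]
  if (!is.null(subset)) scored <- scored[scored$locus_id %in% subset, ]
  if (nrow(scored) == 0L) stop("no scored loci in subset", call. = FALSE)
  idx <- findInterval(scored$nrdi, seq(0, 0.9, by = 0.1))
  counts <- tabulate(idx, nbins = 10L)
  stats::setNames(counts / sum(counts),
                  sprintf("[%.1f,%.1f%s", seq(0, 0.9, 0.1),
                          seq(0.1, 1, 0.1),
                          c(rep(")", 9), "]")))
}

#' Normal repeat range of a cohort's ERCs at one locus
#'
#' `upper_trim` reports `(min, p95)` -- the display range in which only the
#' maximum outliers are excluded; `two_sided` reports `(p5, p95)` -- the
#' database record. Percentiles are nearest-rank as in [trim_counts()].
#'
#' @param ercs integer vector of per-sample ERCs (>= 2 values).
#' @param mode `"upper_trim"` or `"two_sided"`.
#' @return `c(low =, high =)`.
#' @export
normal_range <- function(ercs, mode = c("two_sided", "upper_trim")) {
  mode <- match.arg(mode)
  ercs <- ercs[!is.na(ercs)]
  if (length(ercs) < 2L) {
    stop("need at least 2 non-missing values", call. = FALSE)
  }
  tr <- trim_counts(ercs)
  low <- if (mode == "upper_trim") min(ercs) else tr$p5
  c(low = low, high = tr$p95)
}

#' Repeat-size histogram with a pooled terminal bin
#'
#' Proportion of ERCs at each repeat size `1..cap`, plus one pooled bin for
#' sizes above `cap` (default 30), mirroring the convention of pooling
#' large expansions that exceed the plotting range.
#'
#' @param ercs integer vector of repeat sizes (non-empty; values below 1
#'   are counted in bin 1).
#' @param cap largest individually-binned repeat size (default 30).
#' @return Named numeric vector of `cap + 1` proportions summing to 1.
#' @export
repeat_histogram <- function(ercs, cap = 30L) {
  ercs <- ercs[!is.na(ercs)]
  if (length(ercs) == 0L) stop("no values", call. = FALSE)
  v <- pmax(1L, as.integer(ercs))
  binned <- pmin(v, cap + 1L)
  counts <- tabulate(binned, nbins = cap + 1L)
  stats::setNames(counts / sum(counts), c(as.character(seq_len(cap)),
                                          paste0(cap, "+")))
}
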