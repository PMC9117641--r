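# Per-sample genotyping: read-level repeat counts -> estimated repeat
# count (ERC) per (sample, locus), merged into a population matrix.

#' Estimated repeat count (ERC) from per-read repeat counts
#'
#' The per-read repeat counts at a locus are sorted in decreasing order and
#' the value at 1-based position `ceiling(erc_quantile * N)` is the sample's
#' genotype. The default quantile 0.25 takes the repeat size at the top-25%
#' rank: long-read repeat callers miscount predominantly downwards (truncated
#' repeat traversals), so a high-rank order statistic is more robust than the
#' median. Coverage below `min_coverage` reads (default 8) yields `NA`.
#'
#' @param read_counts integer vector of per-read repeat counts (>= 0).
#' @param min_coverage minimum number of reads required (default 8).
#' @param erc_quantile top-rank fraction in (0, 1) (default 0.25).
#' @return Integer ERC, or `NA_integer_` if coverage is insufficient.
#' @export
#' @examples
#' estimate_erc(c(18, 20, 15, 15, 14, 12, 12, 11))  # 18
estimate_erc <- function(read_counts, min_coverage = 8L,
                         erc_quantile = 0.25) {
  if (length(read_counts) == 0L) return(NA_integer_)
  if (anyNA(read_counts) || any(read_counts < 0) ||
      any(read_counts != floor(read_counts))) {
    stop("read_counts must be non-negative integers", call. = FALSE)
  }
  stopifnot(erc_quantile > 0, erc_quantile < 1)
  n <- length(read_counts)
  if (n < min_coverage) return(NA_integer_)
  idx <- as.integer(ceiling(erc_quantile * n))
  as.integer(sort(read_counts, decreasing = TRUE)[idx])
}

#' Build a locus-by-sample genotype matrix from read observations
#'
#' One cell per (catalog locus, observed sample); each cell is
#' [estimate_erc()] applied to that sample's reads at that locus. Loci with
#' no reads for a sample, or with coverage below `min_coverage`, are `NA`.
#'
#' @param obs read-observation table: data.frame with columns `sample_id`,
#'   `locus_id`, `repeat_count` (one row per aligned read).
#' @param catalog catalog data.table; rows define the loci (matrix rows).
#' @inheritParams estimate_erc
#' @return Integer matrix, rows = catalog loci (in catalog order), columns =
#'   samples (sorted); `NA` marks missing genotypes.
#' @export
build_genotype_matrix <- function(obs, catalog, min_coverage = 8L,
                                  erc_quantile = 0.25) {
  obs <- data.table::as.data.table(obs)
  req <- c("sample_id", "locus_id", "repeat_count")
  miss <- setdiff(req, names(obs))
  if (length(miss)) {
    stop("obs is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  loci <- as.character(catalog$locus_id)
  unknown <- setdiff(unique(obs$locus_id), loci)
  if (length(unknown)) {
    stop("read observations reference unknown locus id(s): ",
         paste(head(unknown, 10L), collapse = ", "),
         if (length(unknown) > 10L) " ..." else "", call. = FALSE)
  }
  samples <- sort(unique(as.character(obs$sample_id)))
  g <- matrix(NA_integer_, nrow = length(loci), ncol = length(samples),
              dimnames = list(loci, samples))
  if (nrow(obs) == 0L) return(g)
  ercs <- obs[, .(erc = estimate_erc(repeat_count,
                                     min_coverage = min_coverage,
                                     erc_quantile = erc_quantile)),
              by = .(locus_id, sample_id)]
  g[cbind(match(ercs$locus_id, loci), match(ercs$sample_id, samples))] <-
    ercs$erc
  g
}

#' Per-(sample, locus) coverage from a read-observation table
#'
#' @inheritParams build_genotype_matrix
#' @return data.table with `locus_id`, `sample_id`, `coverage`.
#' @export
read_coverage <- function(obs) {
  obs <- data.table::as.data.table(obs)
  obs[, .(coverage = .N), by = .(locus_id, sample_id)]
}

#' Concordance between two genotype matrices
#'
#' Pearson correlation over all (locus, sample) cells non-missing in both
#' matrices; used to compare genotypes called from two sequencing platforms
#' or noise regimes.
#'
#' @param a,b genotype matrices with locus rownames and sample colnames.
#' @return `list(pearson_r =, n_pairs =)`.
#' @export
concordance <- function(a, b) {
  loci <- intersect(rownames(a), rownames(b))
  samples <- intersect(colnames(a), colnames(b))
  if (length(loci) == 0L || length(samples) == 0L) {
    stop("matrices share no loci/samples", call. = FALSE)
  }
  x <- a[loci, samples, drop = FALSE]
  y <- b[loci, samples, drop = FALSE]
  ok <- !is.na(x) & !is.na(y)
  xv <- as.numeric(x[ok]); yv <- as.numeric(y[ok])
  if (length(xv) < 2L) {
    stop("fewer than 2 shared non-missing cells", call. = FALSE)
  }
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0) {
    stop("correlation undefined: zero variance in a genotype vector",
         call. = FALSE)
  }
  list(pearson_r = stats::cor(xv, yv), n_pairs = length(xv))
}
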