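# Independent brute-force oracles. These re-derive expected values from
# first principles (explicit sorts, index arithmetic, closed forms) and
# must stay decoupled from the implementation paths they check.

# ERC oracle: ascending sort, then the value sitting ceiling(q*n) positions
# from the top, i.e. ascending index n - ceiling(q*n) + 1.
oracle_erc <- function(v, min_coverage = 8, q = 0.25) {
  n <- length(v)
  if (n < min_coverage) return(NA_integer_)
  asc <- sort(v)
  asc[n - ceiling(q * n) + 1]
}

# Nearest-rank trim bounds on the ascending sort. Products within 1e-9 of
# an integer count as integers; a non-integer upper product never selects
# the maximum (index capped at n - 1).
oracle_trim_bounds <- function(v, lower = 0.05, upper = 0.95) {
  n <- length(v)
  asc <- sort(v)
  lo_prod <- lower * n
  hi_prod <- upper * n
  near_int <- function(x) abs(x - round(x)) < 1e-9
  i_lo <- if (near_int(lo_prod)) round(lo_prod) else ceiling(lo_prod)
  i_lo <- max(1, i_lo)
  if (near_int(hi_prod)) {
    i_hi <- round(hi_prod)
  } else {
    i_hi <- min(ceiling(hi_prod), n - 1)
  }
  i_hi <- max(i_hi, i_lo)
  c(p5 = asc[i_lo], p95 = asc[i_hi])
}

# Full trim -> population-SD pipeline oracle.
oracle_trim_rdi <- function(v, lower = 0.05, upper = 0.95) {
  b <- oracle_trim_bounds(v, lower, upper)
  kept <- v[v >= b["p5"] & v <= b["p95"]]
  sqrt(mean((kept - mean(kept))^2))
}

# Two-sided Fisher p for the 2x2 table (k, n-k / K-k, N-n-K+k): sum of all
# hypergeometric point masses not exceeding the observed one.
oracle_fisher_p <- function(k, K, n, N) {
  xs <- max(0, n + K - N):min(n, K)
  pm <- choose(K, xs) * choose(N - K, n - xs) / choose(N, n)
  p_obs <- pm[xs == k]
  sum(pm[pm <= p_obs * (1 + 1e-7)])
}

# Benjamini-Hochberg step-up by hand.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Closed-form Pearson correlation.
oracle_pearson <- function(x, y) {
  n <- length(x)
  sxy <- sum(x * y) - sum(x) * sum(y) / n
  sxx <- sum(x^2) - sum(x)^2 / n
  syy <- sum(y^2) - sum(y)^2 / n
  sxy / sqrt(sxx * syy)
}

# Tiny catalog + gene model fixtures built in code.
toy_gene <- function(gene_id = "GENEA", chrom = "chr1", strand = "+",
                     tx_start = 10000L, tx_end = 30000L,
                     exons = rbind(c(12000L, 12500L), c(20000L, 20400L)),
                     utrs = rbind(c(10000L, 10120L), c(29880L, 30000L))) {
  data.table::data.table(gene_id = gene_id, chrom = chrom, strand = strand,
                         tx_start = tx_start, tx_end = tx_end,
                         exons = list(exons), utrs = list(utrs))
}

toy_locus <- function(chrom = "chr1", start = 12100L, end = 12130L,
                      locus_id = "L1", motif = "CAG") {
  data.table::data.table(chrom = chrom, start = start, end = end,
                         locus_id = locus_id, motif = motif)
}
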