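# Tissue expression profiling of STR-related gene sets and generic
# Fisher / Benjamini-Hochberg over-representation.

#' Rank-normalize an expression matrix within each tissue
#'
#' Expression levels measured in different tissues are not directly
#' comparable (library depth is fixed per sample), so each tissue column is
#' replaced by ascending midranks scaled to `[0, 1]` via
#' `(rank - 1) / (G - 1)`. The transform is idempotent and invariant under
#' any strictly monotone transform of a column.
#'
#' @param expr numeric genes-by-tissues matrix (rownames = gene ids,
#'   colnames = tissue names; values >= 0).
#' @return Matrix of the same shape with values in `[0, 1]`.
#' @export
rank_normalize <- function(expr) {
  if (nrow(expr) < 2L) {
    stop("rank normalization needs at least 2 genes", call. = FALSE)
  }
  if (any(expr < 0, na.rm = TRUE)) {
    stop("expression values must be non-negative", call. = FALSE)
  }
  G <- nrow(expr)
  out <- apply(expr, 2L, function(col) {
    (rank(col, ties.method = "average") - 1) / (G - 1)
  })
  dimnames(out) <- dimnames(expr)
  out
}

#' Tissue-preference profile of a gene set
#'
#' Scores each tissue by the mean rank-normalized expression of the gene
#' set's members and returns tissues in descending score order. A score
#' above 0.5 means the set sits in the upper half of that tissue's
#' expression distribution.
#'
#' @param normalized rank-normalized matrix from [rank_normalize()].
#' @param gene_set character vector of gene ids.
#' @return data.table with `tissue`, `score`, `n_genes`, sorted by
#'   descending score; attribute `"missing_genes"` lists set members absent
#'   from the matrix.
#' @export
tissue_profile <- function(normalized, gene_set) {
  present <- intersect(gene_set, rownames(normalized))
  if (length(present) == 0L) {
    stop("gene set has no members in the expression matrix", call. = FALSE)
  }
  score <- colMeans(normalized[present, , drop = FALSE])
  out <- data.table::data.table(tissue = names(score),
                                score = as.numeric(score),
                                n_genes = length(present))
  data.table::setorder(out, -score, tissue)
  data.table::setattr(out, "missing_genes", setdiff(gene_set, present))
  out[]
}

#' Per-tissue Fisher test of gene-set association with high expression
#'
#' For each tissue, genes are split at the within-tissue median of the
#' rank-normalized values, and a two-sided Fisher's exact test is applied
#' to the 2x2 table (in set / out of set) x (high / low expression), with
#' Benjamini-Hochberg adjustment across tissues. This operationalizes
#' "which tissues preferentially express the set".
#'
#' @inheritParams tissue_profile
#' @return data.table with `tissue`, `odds_ratio`, `p`, `p_adj`, sorted by
#'   `p_adj` then tissue.
#' @export
tissue_fisher <- function(normalized, gene_set) {
  present <- intersect(gene_set, rownames(normalized))
  if (length(present) == 0L) {
    stop("gene set has no members in the expression matrix", call. = FALSE)
  }
  in_set <- rownames(normalized) %in% present
  rows <- lapply(colnames(normalized), function(tis) {
    high <- normalized[, tis] > stats::median(normalized[, tis])
    tab <- matrix(c(sum(in_set & high), sum(in_set & !high),
                    sum(!in_set & high), sum(!in_set & !high)), nrow = 2L)
    ft <- stats::fisher.test(tab)
    data.table::data.table(tissue = tis,
                           odds_ratio = unname(ft$estimate),
                           p = ft$p.value)
  })
  out <- data.table::rbindlist(rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  data.table::setorder(out, p_adj, tissue)
  out[]
}

#' Gene-set over-representation by Fisher's exact test
#'
#' Each term is tested with a two-sided Fisher's exact test on the 2x2
#' table (in set / out of set) x (in term / out of term) over the universe,
#' with Benjamini-Hochberg adjustment across all tested terms. A term is
#' called significant when `p_adj < alpha` and its odds ratio exceeds 1
#' (over-representation, not depletion).
#'
#' @param gene_set character vector of gene ids; must be a subset of
#'   `universe`.
#' @param terms either a named list of gene-id vectors, or a data.frame
#'   with columns `term`, `gene` (long format).
#' @param universe character vector of gene ids defining the test space;
#'   term memberships are intersected with it.
#' @param alpha significance threshold on the adjusted p-value
#'   (default 0.01).
#' @return data.table with one row per term: `term`, `k` (set-term
#'   overlap), `K` (term size), `n` (set size), `N` (universe size),
#'   `odds_ratio`, `p`, `p_adj`, `significant`; sorted by `p_adj`, `term`.
#' @export
fisher_enrichment <- function(gene_set, terms, universe, alpha = 0.01) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  gene_set <- unique(as.character(gene_set))
  outside <- setdiff(gene_set, universe)
  if (length(outside)) {
    stop("gene_set members outside the universe: ",
         paste(head(outside, 5L), collapse = ", "), call. = FALSE)
  }
  if (is.data.frame(terms)) {
    terms <- split(as.character(terms$gene), as.character(terms$term))
  }
  N <- length(universe)
  n <- length(gene_set)
  rows <- lapply(names(terms), function(tm) {
    tg <- intersect(unique(as.character(terms[[tm]])), universe)
    K <- length(tg)
    if (K == 0L) return(NULL)
    k <- length(intersect(tg, gene_set))
    tab <- matrix(c(k, n - k, K - k, N - n - K + k), nrow = 2L)
    ft <- stats::fisher.test(tab)
    data.table::data.table(term = tm, k = k, K = K, n = n, N = N,
                           odds_ratio = unname(ft$estimate), p = ft$p.value)
  })
  out <- data.table::rbindlist(rows)
  if (nrow(out) == 0L) stop("no testable terms in the universe",
                            call. = FALSE)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p_adj < alpha & out$odds_ratio > 1
  data.table::setorder(out, p_adj, term)
  out[]
}
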