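# STR catalog: motif canonicalization, gene assignment, region
# classification, catalog intersection. Coordinates are 0-based half-open.

REGION_CLASSES <- c("exonic", "utr", "intronic_proximal", "intronic_distal",
                    "upstream", "downstream", "unassigned")

#' Validate STR motifs
#'
#' A motif is a repeat unit of 3-6 uppercase bases over \{A, C, G, T\}.
#'
#' @param motif character vector of candidate motifs.
#' @return Invisibly, `motif`; stops on any invalid entry.
#' @keywords internal
validate_motif <- function(motif) {
  if (!is.character(motif) || anyNA(motif)) {
    stop("motif must be a character vector without NA", call. = FALSE)
  }
  bad <- !grepl("^[ACGT]{3,6}$", motif)
  if (any(bad)) {
    stop("invalid motif(s): ", paste(unique(motif[bad]), collapse = ", "),
         " (need 3-6 uppercase bases over ACGT)", call. = FALSE)
  }
  invisible(motif)
}

#' Reverse complement of a DNA motif
#'
#' @param x character vector over ACGT.
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp("CAG")  # "CTG"
revcomp <- function(x) {
  comp <- chartr("ACGT", "TGCA", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1))
}

rotations <- function(m) {
  n <- nchar(m)
  vapply(seq_len(n) - 1L, function(k) {
    paste0(substr(m, k + 1L, n), substr(m, 1L, k))
  }, character(1))
}

#' Canonical repeat unit of a motif
#'
#' Two motifs describe the same repeat tract if one is a cyclic rotation of
#' the other or of its reverse complement (a repeat read on the opposite
#' strand or started at a different offset). The canonical unit is the
#' lexicographically smallest string in that equivalence class, so e.g. CAG,
#' AGC, GCA, CTG, TGC and GCT all map to "AGC".
#'
#' @param motif character vector of motifs (3-6 bases over ACGT).
#' @return Character vector of class representatives, same length as `motif`.
#' @export
#' @examples
#' canonical_unit(c("CAG", "CTG"))  # both "AGC"
canonical_unit <- function(motif) {
  validate_motif(motif)
  vapply(motif, function(m) {
    min(c(rotations(m), rotations(revcomp(m))))
  }, character(1), USE.NAMES = FALSE)
}

# Gap between half-open intervals [a1,a2) and [b1,b2); 0 when they overlap.
interval_gap <- function(a1, a2, b1, b2) {
  pmax(0L, pmax(b1 - a2, a1 - b2))
}

intervals_overlap <- function(a1, a2, b1, b2) {
  a1 < b2 & b1 < a2
}

#' Assign the nearest gene to an STR locus
#'
#' A locus is assigned to the gene whose body (`[tx_start, tx_end)`)
#' overlaps it (distance 0); otherwise to the gene with the smallest gap,
#' provided the gap is at most `max_distance` (default 10 kb). Ties on gap
#' are broken by lexicographic `gene_id` for determinism.
#'
#' @param locus a one-row data.frame/list with `chrom`, `start`, `end`.
#' @param genes gene-model table as returned by [read_gene_models()]:
#'   columns `gene_id`, `chrom`, `strand`, `tx_start`, `tx_end`, plus
#'   list-columns `exons`, `utrs` of two-column matrices.
#' @param max_distance maximum gap in bp for an assignment (default 10000).
#' @return `list(gene_id =, gene_distance =)`; both `NA` when no gene is
#'   within range.
#' @export
assign_gene <- function(locus, genes, max_distance = 10000L) {
  cand <- genes[genes$chrom == locus$chrom, , drop = FALSE]
  if (nrow(cand) == 0L) {
    return(list(gene_id = NA_character_, gene_distance = NA_integer_))
  }
  gap <- interval_gap(locus$start, locus$end, cand$tx_start, cand$tx_end)
  keep <- gap <= max_distance
  if (!any(keep)) {
    return(list(gene_id = NA_character_, gene_distance = NA_integer_))
  }
  cand <- cand[keep, , drop = FALSE]
  gap <- gap[keep]
  ord <- order(gap, cand$gene_id)
  list(gene_id = cand$gene_id[ord[1L]],
       gene_distance = as.integer(gap[ord[1L]]))
}

#' Classify the genomic region of a locus relative to its assigned gene
#'
#' Priority: exonic > UTR > intronic > flanking. A locus overlapping the
#' gene body is exonic if it intersects any exon interval, else UTR if it
#' intersects a UTR interval, else intronic -- proximal when the distance to
#' the nearest exon boundary is at most `proximal_bp` (default 1 kb),
#' distal otherwise. A locus outside the body is upstream or downstream of
#' the gene, strand-aware.
#'
#' @param locus a one-row data.frame/list with `chrom`, `start`, `end`.
#' @param gene a one-row gene model (same shape as rows of
#'   [read_gene_models()] output).
#' @param proximal_bp intronic proximal/distal split distance (default 1000).
#' @return One of `"exonic"`, `"utr"`, `"intronic_proximal"`,
#'   `"intronic_distal"`, `"upstream"`, `"downstream"`.
#' @export
classify_region <- function(locus, gene, proximal_bp = 1000L) {
  if (locus$chrom != gene$chrom) {
    stop("locus and gene are on different chromosomes", call. = FALSE)
  }
  exons <- if (is.list(gene$exons) && !is.matrix(gene$exons)) gene$exons[[1L]] else gene$exons
  utrs <- if (is.list(gene$utrs) && !is.matrix(gene$utrs)) gene$utrs[[1L]] else gene$utrs
  s <- locus$start; e <- locus$end
  if (!intervals_overlap(s, e, gene$tx_start, gene$tx_end)) {
    before <- e <= gene$tx_start
    if (gene$strand == "+") {
      return(if (before) "upstream" else "downstream")
    }
    return(if (before) "downstream" else "upstream")
  }
  if (!is.null(exons) && nrow(exons) > 0L &&
      any(intervals_overlap(s, e, exons[, 1L], exons[, 2L]))) {
    return("exonic")
  }
  if (!is.null(utrs) && nrow(utrs) > 0L &&
      any(intervals_overlap(s, e, utrs[, 1L], utrs[, 2L]))) {
    return("utr")
  }
  # intronic: distance from the locus interval to the nearest exon boundary
  if (is.null(exons) || nrow(exons) == 0L) {
    return("intronic_distal")
  }
  bnd <- c(exons[, 1L], exons[, 2L])
  d <- pmin(abs(bnd - s), abs(bnd - (e - 1L)))
  d[bnd >= s & bnd < e] <- 0L
  if (min(d) <= proximal_bp) "intronic_proximal" else "intronic_distal"
}

#' Annotate a catalog with gene assignment and region class
#'
#' Applies [assign_gene()] and [classify_region()] to every locus and fills
#' the `gene_id`, `gene_distance`, and `region_class` columns; loci with no
#' gene within 10 kb are `unassigned`.
#'
#' @param catalog catalog data.table (see [read_catalog()]).
#' @param genes gene-model table (see [read_gene_models()]).
#' @inheritParams assign_gene
#' @inheritParams classify_region
#' @return The catalog with annotation columns filled, as a data.table.
#' @export
annotate_catalog <- function(catalog, genes, max_distance = 10000L,
                             proximal_bp = 1000L) {
  catalog <- data.table::as.data.table(catalog)
  n <- nrow(catalog)
  gid <- character(n); gdist <- integer(n); rc <- character(n)
  for (i in seq_len(n)) {
    loc <- catalog[i]
    hit <- assign_gene(loc, genes, max_distance = max_distance)
    gid[i] <- hit$gene_id
    gdist[i] <- hit$gene_distance
    if (is.na(hit$gene_id)) {
      rc[i] <- "unassigned"
    } else {
      g <- genes[genes$gene_id == hit$gene_id, , drop = FALSE]
      rc[i] <- classify_region(loc, g[1L, , drop = FALSE],
                               proximal_bp = proximal_bp)
    }
  }
  catalog$gene_id <- gid
  catalog$gene_distance <- gdist
  catalog$region_class <- factor(rc, levels = REGION_CLASSES)
  catalog[]
}

#' Pair loci of two catalogs that share position and repeat unit
#'
#' Pairs loci whose intervals intersect on the same chromosome and whose
#' canonical repeat units match. Pairing is greedy by largest overlap
#' (ties: smallest start, then locus ids), and each locus appears in at
#' most one pair.
#'
#' @param a,b catalog data.tables with columns `chrom`, `start`, `end`,
#'   `locus_id`, `motif` (and optionally `canonical_unit`, computed if
#'   absent).
#' @return data.table with columns `locus_a`, `locus_b`, `overlap_bp`.
#' @export
overlap_catalog <- function(a, b) {
  a <- data.table::as.data.table(a); b <- data.table::as.data.table(b)
  for (nm in c("a", "b")) {
    x <- get(nm)
    if (is.null(x$canonical_unit) || anyNA(x$canonical_unit)) {
      x$canonical_unit <- canonical_unit(x$motif)
      assign(nm, x)
    }
  }
  empty <- data.table::data.table(locus_a = character(),
                                  locus_b = character(),
                                  overlap_bp = integer())
  if (nrow(a) == 0L || nrow(b) == 0L) return(empty)
  bx <- b[, .(chrom, start, end, locus_id, canonical_unit)]
  ax <- a[, .(chrom, start, end, locus_id, canonical_unit)]
  data.table::setkey(bx, chrom, start, end)
  ov <- data.table::foverlaps(ax, bx, type = "any", nomatch = NULL)
  # foverlaps keys are closed intervals; drop abutting half-open pairs
  ov <- ov[i.start < end & start < i.end & canonical_unit == i.canonical_unit]
  if (nrow(ov) == 0L) return(empty)
  cand <- ov[, .(locus_a = i.locus_id, locus_b = locus_id,
                 start_a = i.start, start_b = start,
                 overlap_bp = as.integer(pmin(end, i.end) -
                                         pmax(start, i.start)))]
  data.table::setorder(cand, -overlap_bp, start_a, start_b, locus_a, locus_b)
  used_a <- character(0); used_b <- character(0)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    la <- cand$locus_a[i]; lb <- cand$locus_b[i]
    if (!(la %in% used_a) && !(lb %in% used_b)) {
      keep[i] <- TRUE
      used_a <- c(used_a, la); used_b <- c(used_b, lb)
    }
  }
  out <- cand[keep, .(locus_a, locus_b, overlap_bp)]
  data.table::setorder(out, locus_a)
  out[]
}
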