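# Shared tabular I/O. Everything is TSV, "NA" marks missing values, gzip
# is transparent by extension, and column order on write is deterministic.
# Coordinates in files follow the BED convention (0-based half-open).

# fread with gzip handled via a connection (no R.utils dependency)
fread_tsv <- function(path, na.strings = "NA") {
  if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "rt")
    on.exit(close(con))
    txt <- paste(readLines(con), collapse = "\n")
    data.table::fread(text = txt, sep = "\t", header = TRUE,
                      na.strings = na.strings, showProgress = FALSE)
  } else {
    data.table::fread(path, sep = "\t", header = TRUE,
                      na.strings = na.strings, showProgress = FALSE)
  }
}

#' Read a typed TSV table
#'
#' @param path file path (`.gz` handled transparently).
#' @param required_cols character vector of columns that must be present.
#' @param integer_cols columns validated as integer; a malformed value
#'   raises an error naming the 1-based data line.
#' @return data.table.
#' @export
read_table <- function(path, required_cols = NULL, integer_cols = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- fread_tsv(path)
  if (!is.null(required_cols)) {
    miss <- setdiff(required_cols, names(tab))
    extra_note <- ""
    if (length(miss)) {
      stop(basename(path), ": missing column(s): ",
           paste(miss, collapse = ", "), extra_note, call. = FALSE)
    }
  }
  for (col in intersect(integer_cols, names(tab))) {
    v <- tab[[col]]
    if (is.integer(v)) next
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & (is.na(num) | num != floor(num)))
    if (length(bad)) {
      stop(basename(path), ": column '", col,
           "' has a non-integer value on line ", bad[1L] + 1L,
           " ('", v[bad[1L]], "')", call. = FALSE)
    }
    data.table::set(tab, j = col, value = as.integer(num))
  }
  tab
}

#' Write a table as TSV
#'
#' @param tab data.frame/data.table.
#' @param path output path; `.gz` compresses.
#' @return Invisibly, `path`.
#' @export
write_table <- function(tab, path) {
  data.table::fwrite(tab, path, sep = "\t", na = "NA", quote = FALSE,
                     compress = if (grepl("\\.gz$", path)) "gzip" else "none")
  invisible(path)
}

#' Read an STR catalog (BED6-extended TSV)
#'
#' Columns: `chrom`, `start`, `end`, `locus_id`, `motif`, optional
#' `canonical_unit` (computed when absent or blank), optional annotation
#' columns `gene_id`, `gene_distance`, `region_class`. A leading header
#' line may start with `#`.
#'
#' @param path catalog file path.
#' @return Catalog data.table.
#' @export
read_catalog <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  first <- readLines(con, n = 1L)
  close(con)
  tab <- fread_tsv(path, na.strings = c("NA", ""))
  if (startsWith(first, "#")) {
    data.table::setnames(tab, 1L, sub("^#", "", names(tab)[1L]))
  }
  req <- c("chrom", "start", "end", "locus_id", "motif")
  miss <- setdiff(req, names(tab))
  if (length(miss)) {
    stop("catalog ", basename(path), " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (any(tab$start >= tab$end)) {
    stop("catalog has loci with start >= end (coordinates are 0-based ",
         "half-open)", call. = FALSE)
  }
  if (anyDuplicated(tab$locus_id)) {
    stop("catalog has duplicated locus_id values", call. = FALSE)
  }
  validate_motif(tab$motif)
  if (is.null(tab$canonical_unit)) {
    tab$canonical_unit <- canonical_unit(tab$motif)
  } else {
    blank <- is.na(tab$canonical_unit)
    if (any(blank)) {
      tab$canonical_unit[blank] <- canonical_unit(tab$motif[blank])
    }
  }
  if (!is.null(tab$region_class)) {
    tab$region_class <- factor(tab$region_class, levels = REGION_CLASSES)
  }
  tab
}

#' Write an STR catalog
#'
#' @param catalog catalog data.table.
#' @param path output path; the header line is prefixed with `#`.
#' @return Invisibly, `path`.
#' @export
write_catalog <- function(catalog, path) {
  out <- data.table::as.data.table(catalog)
  front <- c("chrom", "start", "end", "locus_id", "motif", "canonical_unit")
  data.table::setcolorder(out, intersect(c(front, names(out)), names(out)))
  data.table::setnames(out, 1L, paste0("#", names(out)[1L]))
  data.table::fwrite(out, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

# "start-end,start-end" <-> 2-column integer matrix
format_intervals <- function(m) {
  if (is.null(m) || nrow(m) == 0L) return("")
  paste(sprintf("%d-%d", m[, 1L], m[, 2L]), collapse = ",")
}

parse_intervals <- function(s) {
  if (is.na(s) || !nzchar(s)) return(matrix(integer(0), ncol = 2L))
  parts <- strsplit(strsplit(s, ",", fixed = TRUE)[[1L]], "-", fixed = TRUE)
  m <- do.call(rbind, lapply(parts, function(p) as.integer(p)))
  if (any(is.na(m)) || ncol(m) != 2L || any(m[, 1L] >= m[, 2L])) {
    stop("malformed interval list: ", s, call. = FALSE)
  }
  m
}

#' Read gene models from a minimal TSV
#'
#' Columns: `gene_id`, `chrom`, `strand`, `tx_start`, `tx_end`, `exons`,
#' `utrs`; the last two are comma-joined `start-end` interval lists
#' (0-based half-open).
#'
#' @param path gene-model file path.
#' @return data.table with list-columns `exons`, `utrs`.
#' @export
read_gene_models <- function(path) {
  tab <- read_table(path, required_cols = c("gene_id", "chrom", "strand",
                                            "tx_start", "tx_end",
                                            "exons", "utrs"),
                    integer_cols = c("tx_start", "tx_end"))
  tab$exons <- lapply(as.character(tab$exons), parse_intervals)
  tab$utrs <- lapply(as.character(tab$utrs), parse_intervals)
  tab
}

#' Write gene models to a minimal TSV
#'
#' @param genes gene-model data.table (list-columns `exons`, `utrs`).
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_gene_models <- function(genes, path) {
  out <- data.table::data.table(
    gene_id = genes$gene_id, chrom = genes$chrom, strand = genes$strand,
    tx_start = genes$tx_start, tx_end = genes$tx_end,
    exons = vapply(genes$exons, format_intervals, character(1)),
    utrs = vapply(genes$utrs, format_intervals, character(1))
  )
  write_table(out, path)
}

#' Read a read-observation table
#'
#' @param path TSV with columns `sample_id`, `locus_id`, `repeat_count`.
#' @return data.table; malformed repeat counts raise an error with the
#'   offending line number.
#' @export
read_reads <- function(path) {
  tab <- read_table(path,
                    required_cols = c("sample_id", "locus_id",
                                      "repeat_count"),
                    integer_cols = "repeat_count")
  if (any(tab$repeat_count < 0, na.rm = TRUE)) {
    stop(basename(path), ": negative repeat_count values", call. = FALSE)
  }
  tab
}

#' Read / write a genotype matrix TSV
#'
#' First column `locus_id`, remaining columns one per sample, `NA` for
#' missing genotypes.
#'
#' @param path file path.
#' @return Integer matrix with locus rownames and sample colnames.
#' @export
read_genotype_matrix <- function(path) {
  tab <- read_table(path, required_cols = "locus_id")
  loci <- as.character(tab$locus_id)
  tab[, locus_id := NULL]
  m <- as.matrix(tab)
  storage.mode(m) <- "integer"
  rownames(m) <- loci
  m
}

#' @rdname read_genotype_matrix
#' @param gmat genotype matrix.
#' @return `write_genotype_matrix`: invisibly, `path`.
#' @export
write_genotype_matrix <- function(gmat, path) {
  out <- data.table::data.table(locus_id = rownames(gmat))
  out <- cbind(out, data.table::as.data.table(gmat))
  write_table(out, path)
}

#' Read / write an expression matrix TSV
#'
#' First column `gene_id`, remaining columns one per tissue.
#'
#' @param path file path.
#' @return Numeric matrix with gene rownames and tissue colnames.
#' @export
read_expression <- function(path) {
  tab <- read_table(path, required_cols = "gene_id")
  genes <- as.character(tab$gene_id)
  tab[, gene_id := NULL]
  m <- as.matrix(tab)
  storage.mode(m) <- "double"
  rownames(m) <- genes
  m
}

#' @rdname read_expression
#' @param expr expression matrix.
#' @return `write_expression`: invisibly, `path`.
#' @export
write_expression <- function(expr, path) {
  out <- data.table::data.table(gene_id = rownames(expr))
  out <- cbind(out, data.table::as.data.table(expr))
  write_table(out, path)
}

#' Read a term-to-gene annotation table
#'
#' @param path TSV with columns `term`, `gene` (long format).
#' @return data.table.
#' @export
read_terms <- function(path) {
  read_table(path, required_cols = c("term", "gene"))
}
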