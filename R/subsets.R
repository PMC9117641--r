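# Locus-subset profiling: stratify the catalog, intersect named subsets
# (dSTR / eSTR / FM-eSTR lists) with variability results, summarize tier
# composition and decile distributions.

SUBSET_SOURCES <- c("dstr", "estr", "fm_estr", "motif_size", "region",
                    "unit", "custom")

#' Construct a locus subset
#'
#' @param name subset name (non-empty).
#' @param locus_ids character vector of locus ids (de-duplicated).
#' @param source one of `"dstr"`, `"estr"`, `"fm_estr"`, `"motif_size"`,
#'   `"region"`, `"unit"`, `"custom"`.
#' @return A `locus_subset` list.
#' @export
locus_subset <- function(name, locus_ids, source = "custom") {
  stopifnot(is.character(name), nzchar(name))
  source <- match.arg(source, SUBSET_SOURCES)
  structure(list(name = name, locus_ids = unique(as.character(locus_ids)),
                 source = source),
            class = "locus_subset")
}

#' Stratify a catalog into disjoint subsets
#'
#' Partitions the catalog by motif size (3/4/5/6 bp), genomic region class,
#' or canonical repeat unit; every locus lands in exactly one subset.
#'
#' @param catalog annotated catalog data.table.
#' @param by `"motif_size"`, `"region"`, or `"canonical_unit"`.
#' @return Named list of [locus_subset()] objects.
#' @export
build_strata <- function(catalog,
                         by = c("motif_size", "region", "canonical_unit")) {
  by <- match.arg(by)
  key <- switch(by,
    motif_size = paste0(nchar(catalog$motif), "bp"),
    region = as.character(catalog$region_class),
    canonical_unit = {
      cu <- catalog$canonical_unit
      if (is.null(cu) || anyNA(cu)) cu <- canonical_unit(catalog$motif)
      cu
    })
  source <- switch(by, motif_size = "motif_size", region = "region",
                   canonical_unit = "unit")
  ids <- split(as.character(catalog$locus_id), key)
  out <- lapply(names(ids), function(nm) {
    locus_subset(nm, ids[[nm]], source = source)
  })
  stats::setNames(out, names(ids))
}

#' Summarize variability-tier composition of a locus subset
#'
#' Tier and decile proportions are computed over the scored members of the
#' subset only (loci that failed the coverage/fraction rules are counted in
#' `n_unscored`, not in the proportions).
#'
#' @param records variability table from [score_variability()].
#' @param subset a [locus_subset()] or a character vector of locus ids.
#' @return List with `name`, `n_loci_scored`, `n_unscored`,
#'   `tier_proportions` (5 values), `decile_proportions` (10 values).
#' @export
summarize_subset <- function(records, subset) {
  if (is.character(subset)) subset <- locus_subset("subset", subset)
  in_sub <- records[records$locus_id %in% subset$locus_ids, ]
  scored <- in_sub[!is.na(in_sub$nrdi), ]
  if (nrow(scored) == 0L) {
    stop("subset '", subset$name, "' has no scored loci", call. = FALSE)
  }
  tier_counts <- table(factor(scored$tier, levels = TIER_LEVELS))
  list(
    name = subset$name,
    n_loci_scored = nrow(scored),
    n_unscored = nrow(in_sub) - nrow(scored),
    tier_proportions = as.numeric(tier_counts) / nrow(scored),
    decile_proportions = unname(decile_distribution(records,
                                                    subset$locus_ids))
  )
}

#' Summarize several subsets into one table
#'
#' @param records variability table from [score_variability()].
#' @param subsets list of [locus_subset()] objects.
#' @return data.table: one row per subset with tier and decile proportion
#'   columns (`tier_vlSTR`..`tier_vhSTR`, `decile_1`..`decile_10`).
#' @export
summarize_subsets <- function(records, subsets) {
  rows <- lapply(subsets, function(s) {
    sm <- summarize_subset(records, s)
    row <- data.table::data.table(name = sm$name,
                                  n_loci_scored = sm$n_loci_scored,
                                  n_unscored = sm$n_unscored)
    tp <- as.list(sm$tier_proportions)
    names(tp) <- paste0("tier_", TIER_LEVELS)
    dp <- as.list(sm$decile_proportions)
    names(dp) <- paste0("decile_", seq_len(10L))
    cbind(row, data.table::as.data.table(tp), data.table::as.data.table(dp))
  })
  data.table::rbindlist(rows)
}

#' Resolve a subset file against a catalog
#'
#' Subset files may name loci by `locus_id` or by `(chrom, start, end)`
#' coordinates; coordinate rows are matched exactly against the catalog.
#' Unresolvable entries are reported with a warning, not fatal.
#'
#' @param path TSV with either a `locus_id` column or `chrom`, `start`,
#'   `end` columns; an optional `name` column names the subset (otherwise
#'   the file stem is used).
#' @param catalog catalog data.table to resolve against.
#' @param source subset source tag (see [locus_subset()]).
#' @return A [locus_subset()].
#' @export
read_subset <- function(path, catalog, source = "custom") {
  tab <- read_table(path)
  nm <- if ("name" %in% names(tab) && nrow(tab) > 0L) {
    as.character(tab$name[1L])
  } else {
    sub("\\.[^.]*$", "", basename(path))
  }
  if ("locus_id" %in% names(tab)) {
    wanted <- as.character(tab$locus_id)
    found <- wanted %in% catalog$locus_id
  } else if (all(c("chrom", "start", "end") %in% names(tab))) {
    key <- paste(catalog$chrom, catalog$start, catalog$end)
    qk <- paste(tab$chrom, tab$start, tab$end)
    idx <- match(qk, key)
    found <- !is.na(idx)
    wanted <- ifelse(found, as.character(catalog$locus_id[idx]), qk)
  } else {
    stop("subset file needs a locus_id column or chrom/start/end columns",
         call. = FALSE)
  }
  if (any(!found)) {
    warning(sum(!found), " subset entr",
            if (sum(!found) == 1L) "y" else "ies",
            " could not be resolved against the catalog: ",
            paste(head(wanted[!found], 5L), collapse = ", "),
            call. = FALSE)
  }
  locus_subset(nm, wanted[found], source = source)
}
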