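# End-to-end pipeline: genotype -> score -> subsets -> tissue -> enrich,
# driven by one configuration, with a JSON manifest of everything written.

#' Build a run configuration
#'
#' Holds the input paths and the pipeline constants. Defaults are the
#' standard analysis constants: 8x minimum coverage, top-25% ERC rank,
#' 5%/95% trim bounds, 0.8 minimum genotyped fraction, adjusted-p
#' threshold 0.01.
#'
#' @param catalog,reads paths to the catalog and read-observation TSVs
#'   (required).
#' @param subsets named character vector/list of subset TSV paths
#'   (optional).
#' @param expression,terms paths to the expression matrix and term table
#'   (optional; enable the tissue/enrichment stages).
#' @param outdir output directory.
#' @param min_coverage,erc_quantile,trim_lower,trim_upper,min_fraction,alpha
#'   pipeline constants (see Description).
#' @param seed integer seed recorded in the manifest.
#' @return A `run_config` list.
#' @export
run_config <- function(catalog, reads, subsets = NULL, expression = NULL,
                       terms = NULL, outdir = ".", min_coverage = 8L,
                       erc_quantile = 0.25, trim_lower = 0.05,
                       trim_upper = 0.95, min_fraction = 0.8, alpha = 0.01,
                       seed = 1L) {
  stopifnot(erc_quantile > 0, erc_quantile < 1,
            trim_lower > 0, trim_upper < 1, trim_lower < trim_upper,
            alpha > 0, alpha < 1, min_coverage >= 1)
  structure(list(catalog = catalog, reads = reads, subsets = subsets,
                 expression = expression, terms = terms, outdir = outdir,
                 min_coverage = as.integer(min_coverage),
                 erc_quantile = erc_quantile, trim_lower = trim_lower,
                 trim_upper = trim_upper, min_fraction = min_fraction,
                 alpha = alpha, seed = as.integer(seed)),
            class = "run_config")
}

#' Load a run configuration from a JSON file
#'
#' Every [run_config()] field can be given in the JSON object; omitted
#' fields take their defaults.
#'
#' @param path JSON config path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(run_config))
  extra <- setdiff(names(cfg), known)
  if (length(extra)) {
    stop("unknown config field(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  do.call(run_config, cfg)
}

#' Run the full STR variability pipeline
#'
#' Chains genotyping, variability scoring, subset summaries, and (when
#' expression/terms inputs are configured) tissue profiling and
#' enrichment of the genes near highly variable loci (hSTR + vhSTR
#' tiers). Writes result TSVs plus `manifest.json` (package version,
#' parameters, input checksums, per-stage row counts) into
#' `config$outdir`.
#'
#' @param config a [run_config()] or path to a JSON config file.
#' @param quiet suppress per-stage log lines (default FALSE).
#' @return Invisibly, the manifest as a list.
#' @export
run_report <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message("[strvar] ", ...)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  outputs <- list()
  stages <- list()

  say("reading catalog: ", config$catalog)
  catalog <- read_catalog(config$catalog)
  gene_map <- if (!is.null(catalog$gene_id)) {
    stats::setNames(as.character(catalog$gene_id), catalog$locus_id)
  }

  say("genotyping: ", config$reads)
  obs <- read_reads(config$reads)
  gmat <- build_genotype_matrix(obs, catalog,
                                min_coverage = config$min_coverage,
                                erc_quantile = config$erc_quantile)
  cells_called <- sum(!is.na(gmat))
  covered <- nrow(unique(obs[, c("locus_id", "sample_id")]))
  stages$genotype <- list(input_reads = nrow(obs),
                          cells_covered = covered,
                          cells_filtered_low_coverage =
                            covered - cells_called,
                          cells_called = cells_called)
  say("  ", nrow(obs), " reads -> ", cells_called, " genotypes (",
      covered - cells_called, " cells below ", config$min_coverage,
      "x coverage)")
  outputs$genotypes <- file.path(config$outdir, "genotypes.tsv")
  write_genotype_matrix(gmat, outputs$genotypes)

  say("scoring variability")
  records <- score_variability(gmat, min_fraction = config$min_fraction,
                               lower = config$trim_lower,
                               upper = config$trim_upper)
  n_scored <- sum(!is.na(records$nrdi))
  stages$score <- list(loci_in = nrow(records), loci_scored = n_scored,
                       loci_unscored = nrow(records) - n_scored)
  say("  ", n_scored, "/", nrow(records), " loci scored")
  outputs$variability <- file.path(config$outdir, "variability.tsv")
  write_table(records, outputs$variability)

  say("subset summaries")
  subsets <- c(build_strata(catalog, "motif_size"),
               build_strata(catalog, "region"))
  if (!is.null(config$subsets)) {
    named <- lapply(seq_along(config$subsets), function(i) {
      read_subset(config$subsets[[i]], catalog)
    })
    subsets <- c(subsets, named)
  }
  scored_ids <- records$locus_id[!is.na(records$nrdi)]
  subsets <- Filter(function(s) any(s$locus_ids %in% scored_ids), subsets)
  summaries <- summarize_subsets(records, subsets)
  stages$subsets <- list(subsets_summarized = nrow(summaries))
  outputs$subset_summaries <- file.path(config$outdir,
                                        "subset_summaries.tsv")
  write_table(summaries, outputs$subset_summaries)

  hv_ids <- records$locus_id[!is.na(records$tier) &
                             records$tier %in% c("hSTR", "vhSTR")]
  hv_genes <- if (!is.null(gene_map)) {
    sort(unique(gene_map[hv_ids][!is.na(gene_map[hv_ids])]))
  } else {
    character(0)
  }

  if (!is.null(config$expression)) {
    say("tissue profile of highly variable STR genes (",
        length(hv_genes), " genes)")
    expr <- read_expression(config$expression)
    normalized <- rank_normalize(expr)
    profile <- tissue_profile(normalized, hv_genes)
    fis <- tissue_fisher(normalized, hv_genes)
    profile <- merge(profile, fis, by = "tissue", sort = FALSE)
    data.table::setorder(profile, -score)
    stages$tissue <- list(genes_profiled = profile$n_genes[1L],
                          tissues = nrow(profile))
    outputs$tissue_profile <- file.path(config$outdir,
                                        "tissue_profile.tsv")
    write_table(profile, outputs$tissue_profile)
  }

  if (!is.null(config$terms)) {
    say("enrichment of highly variable STR genes")
    terms <- read_terms(config$terms)
    universe <- if (!is.null(gene_map)) {
      sort(unique(gene_map[!is.na(gene_map)]))
    } else {
      sort(unique(as.character(terms$gene)))
    }
    enr <- fisher_enrichment(intersect(hv_genes, universe), terms,
                             universe, alpha = config$alpha)
    stages$enrich <- list(terms_tested = nrow(enr),
                          terms_significant = sum(enr$significant))
    say("  ", sum(enr$significant), "/", nrow(enr),
        " terms significant at adjusted p < ", config$alpha)
    outputs$enrichment <- file.path(config$outdir, "enrichment.tsv")
    write_table(enr, outputs$enrichment)
  }

  inputs <- Filter(Negate(is.null),
                   config[c("catalog", "reads", "expression", "terms")])
  inputs <- c(inputs, as.list(unlist(config$subsets)))
  manifest <- list(
    package = "strvar",
    version = as.character(utils::packageVersion("strvar")),
    parameters = config[c("min_coverage", "erc_quantile", "trim_lower",
                          "trim_upper", "min_fraction", "alpha", "seed")],
    inputs = lapply(inputs, function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    }),
    stages = stages,
    outputs = lapply(unname(outputs), identity)
  )
  manifest_path <- file.path(config$outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  say("manifest: ", manifest_path)
  invisible(manifest)
}
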