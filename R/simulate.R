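# Seeded synthetic-data generators: STR catalogs with toy gene models,
# cohort read observations under an undercount-biased noise model, and
# tissue expression matrices with a plantable tissue preference. Every
# generator is a pure function of (parameters, seed) and emits ground
# truth for recovery tests.

#' Read-level noise model for simulated repeat counts
#'
#' Emulates the error profile of a long-read repeat caller: read depth is
#' Poisson (default mean 17.5, a typical nanopore cohort depth); each
#' read's repeat count is perturbed with probability `error_rate`; a
#' perturbation has magnitude `1 + Geometric(step_geom_p)` and is negative
#' (an undercount, e.g. a truncated repeat traversal) with probability
#' `undercount_bias`. The default bias 0.8 makes undercalls dominate, the
#' regime in which a high-rank order statistic beats the median as a
#' genotype estimator.
#'
#' @param depth_mean Poisson mean read depth (> 0; default 17.5).
#' @param error_rate probability a read's count is perturbed (default 0.10).
#' @param undercount_bias probability a perturbation is negative
#'   (default 0.8).
#' @param step_geom_p geometric parameter of the perturbation magnitude
#'   (default 0.5; mean extra magnitude `(1 - p) / p`).
#' @return A `noise_model` list.
#' @export
noise_model <- function(depth_mean = 17.5, error_rate = 0.10,
                        undercount_bias = 0.8, step_geom_p = 0.5) {
  stopifnot(depth_mean > 0,
            error_rate >= 0, error_rate <= 1,
            undercount_bias >= 0, undercount_bias <= 1,
            step_geom_p > 0, step_geom_p <= 1)
  structure(list(depth_mean = depth_mean, error_rate = error_rate,
                 undercount_bias = undercount_bias,
                 step_geom_p = step_geom_p),
            class = "noise_model")
}

# Primitive motif of length 3-6 (not a repetition of a shorter unit).
random_motif <- function(len) {
  repeat {
    m <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
               collapse = "")
    periodic <- any(vapply(seq_len(len - 1L), function(p) {
      len %% p == 0L &&
        m == paste(rep(substr(m, 1L, p), len / p), collapse = "")
    }, logical(1)))
    if (!periodic) return(m)
  }
}

#' Simulate an STR catalog with toy gene models
#'
#' Places `n_genes` gene models (each with exons and UTR intervals) along
#' `chrx` chromosomes, then drops `n_loci` STR loci into exons, UTRs,
#' proximal/distal introns, 5'/3' flanks, and intergenic space so that all
#' region classes are represented. Motif lengths are drawn 3-6 bp with
#' tri-/tetranucleotides dominating (~70%), matching genome-wide STR
#' catalogs. The returned catalog is annotated with the package's own
#' [assign_gene()] / [classify_region()] operations.
#'
#' @param n_loci number of STR loci (>= 1).
#' @param n_genes number of gene models (>= 1).
#' @param seed integer RNG seed.
#' @param chroms chromosome names to cycle genes over.
#' @return List with `catalog` (annotated data.table), `genes` (gene-model
#'   data.table with list-columns `exons`, `utrs`), and `placement`
#'   (intended region class per locus, the placement ground truth).
#' @export
simulate_catalog <- function(n_loci, n_genes, seed = 1L,
                             chroms = c("chr1", "chr2", "chr3")) {
  stopifnot(n_loci >= 1L, n_genes >= 1L)
  set.seed(seed)
  cursor <- stats::setNames(rep(10000L, length(chroms)), chroms)
  genes <- vector("list", n_genes)
  for (g in seq_len(n_genes)) {
    chrom <- chroms[((g - 1L) %% length(chroms)) + 1L]
    tx_len <- sample(12000:24000, 1L)
    tx_start <- cursor[[chrom]]
    tx_end <- tx_start + tx_len
    # gap > 2 * 10 kb so intergenic loci can be unassigned
    cursor[[chrom]] <- tx_end + sample(45000:60000, 1L)
    n_ex <- sample(3:5, 1L)
    ex_starts <- tx_start + sort(sample(seq(500L, tx_len - 900L, by = 50L),
                                        n_ex))
    ex_len <- sample(150:350, n_ex, replace = TRUE)
    exons <- cbind(ex_starts, pmin(ex_starts + ex_len, tx_end - 100L))
    # merge any accidental overlap by clipping each exon at the next start
    if (n_ex > 1L) {
      exons[seq_len(n_ex - 1L), 2L] <-
        pmin(exons[seq_len(n_ex - 1L), 2L], exons[2:n_ex, 1L] - 50L)
    }
    exons <- exons[exons[, 2L] > exons[, 1L], , drop = FALSE]
    # UTR intervals: short non-exonic stretches at each end of the body
    utrs <- rbind(c(tx_start, tx_start + 120L),
                  c(tx_end - 120L, tx_end))
    genes[[g]] <- list(gene_id = sprintf("GENE%04d", g), chrom = chrom,
                       strand = sample(c("+", "-"), 1L),
                       tx_start = tx_start, tx_end = tx_end,
                       exons = exons, utrs = utrs)
  }
  genes_dt <- data.table::data.table(
    gene_id = vapply(genes, `[[`, character(1), "gene_id"),
    chrom = vapply(genes, `[[`, character(1), "chrom"),
    strand = vapply(genes, `[[`, character(1), "strand"),
    tx_start = vapply(genes, `[[`, integer(1), "tx_start"),
    tx_end = vapply(genes, `[[`, integer(1), "tx_end"),
    exons = lapply(genes, `[[`, "exons"),
    utrs = lapply(genes, `[[`, "utrs")
  )
  region_weights <- c(exonic = 0.08, utr = 0.06, intronic_proximal = 0.25,
                      intronic_distal = 0.33, upstream = 0.11,
                      downstream = 0.11, unassigned = 0.06)
  placement <- sample(names(region_weights), n_loci, replace = TRUE,
                      prob = region_weights)
  motif_len <- sample(3:6, n_loci, replace = TRUE,
                      prob = c(0.38, 0.32, 0.16, 0.14))
  loci <- vector("list", n_loci)
  for (i in seq_len(n_loci)) {
    g <- genes[[sample(n_genes, 1L)]]
    ml <- motif_len[i]
    tract <- ml * sample(5:15, 1L)
    pos <- switch(placement[i],
      exonic = {
        ex <- g$exons[sample(nrow(g$exons), 1L), ]
        ex[1L] + 5L
      },
      utr = g$utrs[sample(2L, 1L), 1L] + 5L,
      intronic_proximal = {
        # just after the first exon ends (intron, <= 1 kb from boundary)
        g$exons[1L, 2L] + sample(50:400, 1L)
      },
      intronic_distal = {
        # deep inside the widest intron (fall back to the last-exon..end gap)
        gaps <- if (nrow(g$exons) >= 2L) {
          cbind(g$exons[-nrow(g$exons), 2L], g$exons[-1L, 1L])
        } else {
          matrix(integer(0), ncol = 2L)
        }
        gaps <- rbind(gaps, c(g$exons[nrow(g$exons), 2L], g$tx_end - 130L))
        j <- which.max(gaps[, 2L] - gaps[, 1L])
        as.integer(round((gaps[j, 1L] + gaps[j, 2L]) / 2))
      },
      upstream = (if (g$strand == "+") g$tx_start - sample(1500:8000, 1L) - tract
                  else g$tx_end + sample(1500:8000, 1L)),
      downstream = (if (g$strand == "+") g$tx_end + sample(1500:8000, 1L)
                    else g$tx_start - sample(1500:8000, 1L) - tract),
      unassigned = g$tx_end + 20000L + sample(0:5000, 1L)
    )
    loci[[i]] <- list(chrom = g$chrom, start = as.integer(pos),
                      end = as.integer(pos + tract),
                      motif = random_motif(ml))
  }
  catalog <- data.table::data.table(
    chrom = vapply(loci, `[[`, character(1), "chrom"),
    start = vapply(loci, `[[`, integer(1), "start"),
    end = vapply(loci, `[[`, integer(1), "end"),
    locus_id = sprintf("STR%05d", seq_len(n_loci)),
    motif = vapply(loci, `[[`, character(1), "motif")
  )
  catalog$canonical_unit <- canonical_unit(catalog$motif)
  catalog <- annotate_catalog(catalog, genes_dt)
  list(catalog = catalog, genes = genes_dt,
       placement = data.table::data.table(locus_id = catalog$locus_id,
                                          intended_region = placement))
}

#' Simulate per-locus true-genotype models
#'
#' Each locus gets a median true repeat size, a between-sample standard
#' deviation `sigma_true` (the quantity the RDI statistic estimates), and
#' optionally a second population mode, mirroring the single- and
#' multi-peak repeat-size distributions seen at disease-associated loci.
#'
#' @param catalog catalog data.table.
#' @param seed integer RNG seed.
#' @param sigma_max upper bound of the uniform `sigma_true` draw
#'   (default 4).
#' @param bimodal_prob probability a locus is bimodal (default 0.1).
#' @return data.table: `locus_id`, `base_repeat`, `sigma_true`, `n_modes`,
#'   `mode_offset`, `mode_weight`.
#' @export
simulate_locus_models <- function(catalog, seed = 1L, sigma_max = 4,
                                  bimodal_prob = 0.1) {
  set.seed(seed)
  n <- nrow(catalog)
  bim <- stats::runif(n) < bimodal_prob
  data.table::data.table(
    locus_id = as.character(catalog$locus_id),
    base_repeat = sample(8:25, n, replace = TRUE),
    sigma_true = stats::runif(n, 0, sigma_max),
    n_modes = ifelse(bim, 2L, 1L),
    mode_offset = ifelse(bim, sample(5:15, n, replace = TRUE), 0L),
    mode_weight = ifelse(bim, stats::runif(n, 0.2, 0.5), 0)
  )
}

#' Simulate a cohort of per-read repeat-count observations
#'
#' Per sample and locus, the true repeat count is drawn from a discretized
#' (possibly bimodal) normal, floored at 1. Read depth is Poisson, and each
#' read reports the true count perturbed under the [noise_model()]:
#' with probability `error_rate` the count shifts by
#' `1 + Geometric(step_geom_p)`, downward with probability
#' `undercount_bias`, clamped at 0.
#'
#' @param catalog catalog data.table.
#' @param models per-locus models from [simulate_locus_models()].
#' @param n_samples cohort size (default 193, a realistic population-scale
#'   long-read cohort).
#' @param noise a [noise_model()].
#' @param seed integer RNG seed.
#' @return List with `reads` (data.table `sample_id`, `locus_id`,
#'   `repeat_count`), `truth` (loci x samples integer matrix of true
#'   counts), and `models` (echo of the per-locus truth table).
#' @export
simulate_cohort <- function(catalog, models, n_samples = 193L,
                            noise = noise_model(), seed = 1L) {
  stopifnot(inherits(noise, "noise_model"))
  if (!setequal(models$locus_id, catalog$locus_id)) {
    stop("every catalog locus needs a model", call. = FALSE)
  }
  set.seed(seed)
  models <- models[match(catalog$locus_id, models$locus_id), ]
  n_loci <- nrow(catalog)
  samples <- sprintf("S%04d", seq_len(n_samples))
  loci <- as.character(catalog$locus_id)

  base <- matrix(rep(models$base_repeat, n_samples), nrow = n_loci)
  dev <- matrix(stats::rnorm(n_loci * n_samples), nrow = n_loci) *
    models$sigma_true
  second <- matrix(stats::runif(n_loci * n_samples), nrow = n_loci) <
    models$mode_weight
  second <- second & models$n_modes == 2L
  truth <- pmax(1L, as.integer(round(base + dev +
                                     ifelse(second, models$mode_offset, 0L))))
  truth <- matrix(truth, nrow = n_loci, dimnames = list(loci, samples))

  depth <- matrix(stats::rpois(n_loci * n_samples, noise$depth_mean),
                  nrow = n_loci)
  total <- sum(depth)
  cell <- rep.int(seq_len(n_loci * n_samples), as.vector(depth))
  true_per_read <- as.vector(truth)[cell]
  erred <- stats::runif(total) < noise$error_rate
  n_err <- sum(erred)
  shift <- integer(total)
  if (n_err > 0L) {
    mag <- 1L + stats::rgeom(n_err, noise$step_geom_p)
    sgn <- ifelse(stats::runif(n_err) < noise$undercount_bias, -1L, 1L)
    shift[erred] <- mag * sgn
  }
  counts <- pmax(0L, true_per_read + shift)
  li <- ((cell - 1L) %% n_loci) + 1L
  si <- ((cell - 1L) %/% n_loci) + 1L
  reads <- data.table::data.table(sample_id = samples[si],
                                  locus_id = loci[li],
                                  repeat_count = counts)
  data.table::setorder(reads, locus_id, sample_id)
  list(reads = reads, truth = truth, models = models)
}

#' Simulate a genes-by-tissues expression matrix with a planted signal
#'
#' Baseline expression is log-normal per (gene, tissue). The genes of
#' `boosted_set` are shifted upward in `boosted_tissue` by
#' `effect_sd_units` within-tissue standard deviations, planting a
#' recoverable tissue preference (effect 0 gives a null matrix).
#'
#' @param genes character vector of gene ids.
#' @param tissues character vector of tissue names.
#' @param boosted_set subset of `genes` carrying the signal.
#' @param boosted_tissue the preferred tissue (must be in `tissues`).
#' @param effect_sd_units effect size in within-tissue SD units
#'   (default 1.5).
#' @param seed integer RNG seed.
#' @param meanlog,sdlog log-normal baseline parameters (defaults 1, 1).
#' @return List with `expr` (genes x tissues matrix) and the planted
#'   truth (`boosted_set`, `boosted_tissue`, `effect_sd_units`).
#' @export
simulate_expression <- function(genes, tissues, boosted_set = character(0),
                                boosted_tissue = NULL,
                                effect_sd_units = 1.5, seed = 1L,
                                meanlog = 1, sdlog = 1) {
  stopifnot(length(genes) >= 2L, length(tissues) >= 1L,
            all(boosted_set %in% genes),
            is.null(boosted_tissue) || boosted_tissue %in% tissues)
  set.seed(seed)
  expr <- matrix(stats::rlnorm(length(genes) * length(tissues),
                               meanlog = meanlog, sdlog = sdlog),
                 nrow = length(genes),
                 dimnames = list(genes, tissues))
  if (length(boosted_set) && !is.null(boosted_tissue) &&
      effect_sd_units != 0) {
    s <- stats::sd(expr[, boosted_tissue])
    expr[boosted_set, boosted_tissue] <-
      expr[boosted_set, boosted_tissue] + effect_sd_units * s
  }
  list(expr = expr, boosted_set = boosted_set,
       boosted_tissue = boosted_tissue, effect_sd_units = effect_sd_units)
}

#' Simulate a term-to-gene annotation table with one enriched term
#'
#' Background terms draw members uniformly from `genes`; the term
#' `"TERM_ENRICHED"` draws most of its members from `enriched_set`,
#' planting a recoverable over-representation signal.
#'
#' @param genes universe of gene ids.
#' @param enriched_set genes favored by the enriched term.
#' @param n_terms number of background terms (default 20).
#' @param term_size members per term (default 25).
#' @param seed integer RNG seed.
#' @return data.table with columns `term`, `gene`.
#' @export
simulate_terms <- function(genes, enriched_set, n_terms = 20L,
                           term_size = 25L, seed = 1L) {
  set.seed(seed)
  term_size <- min(term_size, length(genes))
  rows <- lapply(seq_len(n_terms), function(i) {
    data.table::data.table(term = sprintf("TERM%03d", i),
                           gene = sample(genes, term_size))
  })
  n_in <- min(length(enriched_set), ceiling(0.8 * term_size))
  enr <- c(sample(enriched_set, n_in),
           sample(setdiff(genes, enriched_set), term_size - n_in))
  rows <- c(rows, list(data.table::data.table(term = "TERM_ENRICHED",
                                              gene = enr)))
  data.table::rbindlist(rows)
}

#' Write a complete simulated input bundle to disk
#'
#' Generates every input the pipeline consumes -- catalog, gene models,
#' read observations, truth tables, a "disease" subset (the top-sigma
#' loci, whose high true variability the pipeline should recover), an
#' expression matrix with a brain-boosted signal over the genes of those
#' loci, and a term table -- and writes them as TSVs under `outdir`.
#'
#' @param outdir output directory (created if absent).
#' @param n_loci,n_samples cohort dimensions (defaults 500, 193).
#' @param n_genes gene models in the catalog (default 60).
#' @param noise a [noise_model()].
#' @param seed integer RNG seed; stage seeds are derived from it.
#' @param tissues tissue names for the expression matrix.
#' @return Invisibly, a named list of written file paths.
#' @export
simulate_inputs <- function(outdir, n_loci = 500L, n_samples = 193L,
                            n_genes = 60L, noise = noise_model(),
                            seed = 1L,
                            tissues = c("brain", "heart", "artery", "lung",
                                        "liver", "kidney", "muscle", "skin",
                                        "blood", "nerve")) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_catalog(n_loci, n_genes, seed = seed)
  models <- simulate_locus_models(sim$catalog, seed = seed + 1L)
  cohort <- simulate_cohort(sim$catalog, models, n_samples = n_samples,
                            noise = noise, seed = seed + 2L)
  # "disease" subset: the 5% most variable loci by true sigma
  n_top <- max(1L, round(0.05 * n_loci))
  top <- models$locus_id[order(-models$sigma_true)][seq_len(n_top)]
  dstr <- data.table::data.table(name = "dstr", locus_id = top)
  genes <- sim$genes$gene_id
  dstr_genes <- unique(sim$catalog$gene_id[sim$catalog$locus_id %in% top &
                                           !is.na(sim$catalog$gene_id)])
  if (length(dstr_genes) == 0L) dstr_genes <- genes[1L]
  exprsim <- simulate_expression(genes, tissues, boosted_set = dstr_genes,
                                 boosted_tissue = tissues[1L],
                                 effect_sd_units = 1.5, seed = seed + 3L)
  terms <- simulate_terms(genes, dstr_genes, seed = seed + 4L)

  paths <- list(
    catalog = file.path(outdir, "catalog.bed"),
    genes = file.path(outdir, "genes.tsv"),
    reads = file.path(outdir, "reads.tsv"),
    truth_genotypes = file.path(outdir, "truth_genotypes.tsv"),
    truth_sigma = file.path(outdir, "truth_sigma.tsv"),
    dstr = file.path(outdir, "dstr.tsv"),
    expression = file.path(outdir, "expr.tsv"),
    terms = file.path(outdir, "terms.tsv")
  )
  write_catalog(sim$catalog, paths$catalog)
  write_gene_models(sim$genes, paths$genes)
  write_table(cohort$reads, paths$reads)
  write_genotype_matrix(cohort$truth, paths$truth_genotypes)
  write_table(models[, .(locus_id, sigma_true)], paths$truth_sigma)
  write_table(dstr, paths$dstr)
  write_expression(exprsim$expr, paths$expression)
  write_table(terms, paths$terms)
  invisible(paths)
}
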