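test_that("generators are pure functions of (parameters, seed)", {
  s1 <- simulate_catalog(80, 10, seed = 5)
  s2 <- simulate_catalog(80, 10, seed = 5)
  expect_identical(s1$catalog, s2$catalog)
  expect_identical(s1$genes$tx_start, s2$genes$tx_start)
  m1 <- simulate_locus_models(s1$catalog, seed = 6)
  c1 <- simulate_cohort(s1$catalog, m1, n_samples = 12, seed = 7)
  c2 <- simulate_cohort(s1$catalog, m1, n_samples = 12, seed = 7)
  expect_identical(c1$reads, c2$reads)
  expect_identical(c1$truth, c2$truth)
  e1 <- simulate_expression(paste0("g", 1:40), paste0("t", 1:3),
                            seed = 8)
  e2 <- simulate_expression(paste0("g", 1:40), paste0("t", 1:3),
                            seed = 8)
  expect_identical(e1$expr, e2$expr)
  # different seed -> different draw
  c3 <- simulate_cohort(s1$catalog, m1, n_samples = 12, seed = 8)
  expect_false(identical(c1$reads, c3$reads))
})

test_that("simulated catalogs represent all region classes and motif lengths", {
  sim <- simulate_catalog(600, 40, seed = 13)
  expect_equal(nrow(sim$catalog), 600L)
  expect_setequal(as.character(unique(sim$catalog$region_class)),
                  c("exonic", "utr", "intronic_proximal",
                    "intronic_distal", "upstream", "downstream",
                    "unassigned"))
  expect_setequal(unique(nchar(sim$catalog$motif)), 3:6)
  expect_true(all(sim$catalog$start < sim$catalog$end))
  expect_false(anyDuplicated(sim$catalog$locus_id) > 0)
})

test_that("noiseless cohorts recover truth exactly at sufficient depth", {
  sim <- simulate_catalog(40, 8, seed = 21)
  models <- simulate_locus_models(sim$catalog, seed = 22)
  quiet <- noise_model(depth_mean = 25, error_rate = 0)
  cohort <- simulate_cohort(sim$catalog, models, n_samples = 15,
                            noise = quiet, seed = 23)
  # every read carries the sample's true count
  truth_long <- data.table::as.data.table(as.table(cohort$truth))
  data.table::setnames(truth_long, c("locus_id", "sample_id", "truth"))
  merged <- merge(cohort$reads, truth_long, by = c("locus_id",
                                                   "sample_id"))
  expect_equal(merged$repeat_count, merged$truth)
  # ERC equals truth wherever coverage reaches 8
  g <- build_genotype_matrix(cohort$reads, sim$catalog)
  ok <- !is.na(g)
  expect_equal(g[ok], cohort$truth[ok])
})

test_that("a zero-sigma locus yields RDI 0 through the pipeline", {
  sim <- simulate_catalog(30, 6, seed = 31)
  models <- simulate_locus_models(sim$catalog, seed = 32)
  models$sigma_true[1] <- 0
  models$n_modes[1] <- 1L
  models$mode_weight[1] <- 0
  quiet <- noise_model(depth_mean = 30, error_rate = 0)
  cohort <- simulate_cohort(sim$catalog, models, n_samples = 20,
                            noise = quiet, seed = 33)
  g <- build_genotype_matrix(cohort$reads, sim$catalog)
  rec <- score_variability(g)
  expect_equal(rec$rdi[rec$locus_id == models$locus_id[1]], 0)
})

test_that("noise magnitudes match the geometric closed form", {
  set.seed(44)
  catalog <- toy_locus(locus_id = "L1")
  models <- data.table::data.table(locus_id = "L1", base_repeat = 1000L,
                                   sigma_true = 0, n_modes = 1L,
                                   mode_offset = 0L, mode_weight = 0)
  noisy <- noise_model(depth_mean = 20, error_rate = 1,
                       undercount_bias = 0.8, step_geom_p = 0.5)
  # ~1e5 reads: base 1000 is far from the 0 clamp so shifts are intact
  cohort <- simulate_cohort(catalog, models, n_samples = 5000L,
                            noise = noisy, seed = 45)
  err <- cohort$reads$repeat_count - 1000L
  expect_true(all(err != 0))  # error_rate 1 perturbs every read
  mag <- abs(err)
  # mean magnitude 1 + (1-p)/p = 2 at p = 0.5
  expect_equal(mean(mag), 2, tolerance = 0.05)
  expect_equal(mean(err < 0), 0.8, tolerance = 0.02)
})

test_that("undercount bias shifts the read median below truth more than the ERC", {
  sim <- simulate_catalog(60, 10, seed = 51)
  models <- simulate_locus_models(sim$catalog, seed = 52)
  heavy <- noise_model(depth_mean = 17.5, error_rate = 0.4,
                       undercount_bias = 0.9)
  cohort <- simulate_cohort(sim$catalog, models, n_samples = 40,
                            noise = heavy, seed = 53)
  g_erc <- build_genotype_matrix(cohort$reads, sim$catalog)
  med <- cohort$reads[, .(m = as.integer(stats::median(repeat_count))),
                      by = .(locus_id, sample_id)]
  g_med <- g_erc
  g_med[cbind(match(med$locus_id, rownames(g_med)),
              match(med$sample_id, colnames(g_med)))] <- med$m
  ok <- !is.na(g_erc)
  mae_erc <- mean(abs(g_erc[ok] - cohort$truth[ok]))
  mae_med <- mean(abs(g_med[ok] - cohort$truth[ok]))
  expect_lte(mae_erc, mae_med)
})

test_that("simulate_expression plants a recoverable or null signal", {
  genes <- paste0("g", 1:150)
  tissues <- paste0("t", 1:8)
  hits <- 0L
  for (s in 1:20) {
    sim <- simulate_expression(genes, tissues, boosted_set = genes[1:25],
                               boosted_tissue = "t4",
                               effect_sd_units = 1.5, seed = 100 + s)
    pr <- tissue_profile(rank_normalize(sim$expr), genes[1:25])
    hits <- hits + (pr$tissue[1] == "t4")
  }
  expect_gte(hits, 19L)
  # null: no planted signal, same pipeline
  null_sim <- simulate_expression(genes, tissues, effect_sd_units = 0,
                                  seed = 7)
  expect_null(null_sim$boosted_tissue)
})

test_that("simulate_inputs writes a round-trippable bundle", {
  d <- withr::local_tempdir()
  paths <- simulate_inputs(d, n_loci = 40, n_samples = 10, n_genes = 8,
                           seed = 61)
  expect_true(all(file.exists(unlist(paths))))
  catalog <- read_catalog(paths$catalog)
  expect_equal(nrow(catalog), 40L)
  reads <- read_reads(paths$reads)
  expect_named(reads, c("sample_id", "locus_id", "repeat_count"))
  truth <- read_genotype_matrix(paths$truth_genotypes)
  expect_equal(dim(truth), c(40L, 10L))
  expr <- read_expression(paths$expression)
  expect_equal(nrow(expr), 8L)
  # byte-identical rerun under the same seed
  d2 <- withr::local_tempdir()
  paths2 <- simulate_inputs(d2, n_loci = 40, n_samples = 10, n_genes = 8,
                            seed = 61)
  for (nm in names(paths)) {
    expect_identical(unname(tools::md5sum(paths[[nm]])),
                     unname(tools::md5sum(paths2[[nm]])),
                     info = nm)
  }
})
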