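test_that("canonical_unit picks the minimal rotation over both strands", {
  # CAG class: rotations {CAG, AGC, GCA} U revcomp rotations {CTG, TGC, GCT}
  expect_equal(canonical_unit("CAG"), "AGC")
  expect_equal(canonical_unit("CTG"), "AGC")
  expect_equal(canonical_unit("AAAAG"), "AAAAG")
  # vectorized and idempotent
  units <- canonical_unit(c("CGG", "CCG", "TTTTA"))
  expect_equal(canonical_unit(units), units)
})

test_that("canonical_unit is a class function over rotations and revcomp", {
  set.seed(42)
  rot <- function(m, k) {
    n <- nchar(m)
    k <- k %% n
    paste0(substr(m, k + 1, n), substr(m, 1, k))
  }
  for (i in 1:50) {
    len <- sample(3:6, 1)
    m <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
               collapse = "")
    cu <- canonical_unit(m)
    for (k in seq_len(len)) {
      expect_equal(canonical_unit(rot(m, k)), cu)
      expect_equal(canonical_unit(rot(revcomp(m), k)), cu)
    }
  }
})

test_that("canonical_unit rejects invalid motifs", {
  expect_error(canonical_unit("CA"), "invalid motif")
  expect_error(canonical_unit("CAGCAGC"), "invalid motif")
  expect_error(canonical_unit("cag"), "invalid motif")
  expect_error(canonical_unit("CAN"), "invalid motif")
})

test_that("assign_gene handles containment, the 10 kb window, and ties", {
  genes <- rbind(toy_gene("GA", tx_start = 10000L, tx_end = 30000L),
                 toy_gene("GB", tx_start = 40000L, tx_end = 60000L))
  # containment -> distance 0
  hit <- assign_gene(list(chrom = "chr1", start = 15000L, end = 15030L),
                     genes)
  expect_equal(hit$gene_id, "GA")
  expect_equal(hit$gene_distance, 0L)
  # 500 bp from GA, 9700 bp from GB -> minimal gap wins
  hit <- assign_gene(list(chrom = "chr1", start = 30500L, end = 30530L),
                     genes)
  expect_equal(hit$gene_id, "GA")
  expect_equal(hit$gene_distance, 500L)
  # strictly beyond 10 kb of the only gene -> none
  far <- assign_gene(list(chrom = "chr1", start = 40001L, end = 40030L),
                     toy_gene("GA", tx_start = 10000L, tx_end = 30000L))
  expect_true(is.na(far$gene_id) && is.na(far$gene_distance))
  # exactly 10 kb is still assigned
  at10k <- assign_gene(list(chrom = "chr1", start = 40000L, end = 40030L),
                       toy_gene("GA", tx_start = 10000L, tx_end = 30000L))
  expect_equal(at10k$gene_distance, 10000L)
  # equal gaps -> lexicographic gene_id
  genes_tie <- rbind(toy_gene("GZ", tx_start = 10000L, tx_end = 20000L),
                     toy_gene("GM", tx_start = 21000L, tx_end = 31000L))
  tie <- assign_gene(list(chrom = "chr1", start = 20485L, end = 20515L),
                     genes_tie)
  expect_equal(tie$gene_id, "GM")
})

test_that("classify_region follows exon > utr > intron > flank priority", {
  g <- toy_gene()  # + strand, exons at 12000-12500 and 20000-20400
  loc <- function(s, e) list(chrom = "chr1", start = s, end = e)
  expect_equal(classify_region(loc(12100L, 12130L), g), "exonic")
  expect_equal(classify_region(loc(10010L, 10040L), g), "utr")
  # intron, 400 bp from exon boundary at 12500
  expect_equal(classify_region(loc(12900L, 12930L), g),
               "intronic_proximal")
  # intron midpoint, > 1 kb from both boundaries
  expect_equal(classify_region(loc(16000L, 16030L), g), "intronic_distal")
  # 2 kb 5' of tx_start on + strand
  expect_equal(classify_region(loc(8000L, 8030L), g), "upstream")
  expect_equal(classify_region(loc(31000L, 31030L), g), "downstream")
  # strand-aware: same positions flip on the - strand
  gm <- toy_gene(strand = "-")
  expect_equal(classify_region(loc(8000L, 8030L), gm), "downstream")
  expect_equal(classify_region(loc(31000L, 31030L), gm), "upstream")
  expect_error(classify_region(list(chrom = "chr2", start = 1L, end = 10L),
                               g), "different chromosomes")
})

test_that("annotate_catalog partitions a catalog into region classes", {
  sim <- simulate_catalog(n_loci = 300, n_genes = 20, seed = 11)
  expect_false(anyNA(sim$catalog$region_class))
  counts <- table(sim$catalog$region_class)
  expect_equal(sum(counts), 300)
  # unassigned iff no gene
  expect_equal(is.na(sim$catalog$gene_id),
               sim$catalog$region_class == "unassigned")
  assigned <- !is.na(sim$catalog$gene_id)
  expect_true(all(sim$catalog$gene_distance[assigned] <= 10000))
})

test_that("overlap_catalog pairs by overlap and canonical unit", {
  a <- rbind(toy_locus(start = 100L, end = 130L, locus_id = "A1",
                       motif = "CAG"),
             toy_locus(start = 500L, end = 560L, locus_id = "A2",
                       motif = "ATAG"))
  # identical catalogs -> identity pairing
  self <- overlap_catalog(a, a)
  expect_equal(self$locus_a, self$locus_b)
  expect_equal(nrow(self), 2L)
  # disjoint -> empty
  b_far <- rbind(toy_locus(start = 9000L, end = 9030L, locus_id = "B1",
                           motif = "CAG"))
  expect_equal(nrow(overlap_catalog(a, b_far)), 0L)
  # unit mismatch blocks an overlapping pair
  b_unit <- rbind(toy_locus(start = 100L, end = 130L, locus_id = "B1",
                            motif = "ATAG"))
  expect_equal(nrow(overlap_catalog(a, b_unit)), 0L)
  # reverse-complement motif still pairs (same canonical unit)
  b_rc <- rbind(toy_locus(start = 110L, end = 140L, locus_id = "B1",
                          motif = "CTG"))
  expect_equal(overlap_catalog(a, b_rc)$locus_b, "B1")
  # one A interval hitting two B intervals -> larger overlap wins
  b_two <- rbind(toy_locus(start = 90L, end = 110L, locus_id = "B_small",
                           motif = "CAG"),
                 toy_locus(start = 105L, end = 130L, locus_id = "B_big",
                           motif = "CAG"))
  pick <- overlap_catalog(a[1], b_two)
  expect_equal(pick$locus_b, "B_big")
  expect_equal(pick$overlap_bp, 25L)
})

test_that("overlap_catalog pair content is symmetric", {
  set.seed(7)
  mk <- function(prefix, n) {
    starts <- sort(sample(1:2000, n)) * 10L
    data.table::data.table(chrom = "chr1", start = starts,
                           end = starts + sample(20:80, n, replace = TRUE),
                           locus_id = paste0(prefix, seq_len(n)),
                           motif = sample(c("CAG", "CTG", "ATAG"), n,
                                          replace = TRUE))
  }
  a <- mk("A", 60); b <- mk("B", 60)
  ab <- overlap_catalog(a, b)
  ba <- overlap_catalog(b, a)
  expect_setequal(paste(ab$locus_a, ab$locus_b),
                  paste(ba$locus_b, ba$locus_a))
  # each locus in at most one pair
  expect_false(anyDuplicated(ab$locus_a) > 0)
  expect_false(anyDuplicated(ab$locus_b) > 0)
})
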