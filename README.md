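# strvar

Population-scale short tandem repeat (STR) variability profiling from
long-read sequencing.

## What it does, and for whom

Long-read repeat callers emit a repeat count *per read* at every
cataloged STR locus in every sample. For anyone building a reference of
normal repeat ranges — to interpret candidate repeat expansions, or to
ask which loci are dynamic in a healthy population — `strvar` turns that
read-level table into population statistics:

1. **Genotyping.** Per (sample, locus), the per-read counts are sorted in
   decreasing order and the value at 1-based index `ceil(0.25·N)` is the
   sample's *estimated repeat count* (ERC). Long-read miscounts are
   undercount-biased, so a top-quartile order statistic resists
   undercalls better than the median. A minimum of 8 reads is required;
   below that the genotype is missing.
2. **Variability scoring.** Per locus, the cohort's ERCs are trimmed to
   the nearest-rank `[p5, p95]` normal range and scored with the *repeat
   dynamic index*,

   RDI = sqrt( Σ (R − R̄)² / N ),

   the population standard deviation of the retained counts. RDI is
   rank-normalized across loci to nRDI ∈ [0, 1] and binned into five
   tiers (vlSTR, lSTR, mSTR, hSTR, vhSTR — 0.2-wide bins), so the full
   catalog is uniform by construction and any subset's excess in the
   upper tiers is signal.
3. **Subset profiling.** Tier and decile distributions of named locus
   subsets (disease-associated STRs, expression STRs, fine-mapped eSTRs)
   and of motif-size / genomic-region / repeat-unit strata.
4. **Expression & enrichment.** Per-tissue rank normalization of a
   genes × tissues matrix, tissue-preference profiles of STR-related
   gene sets, and Fisher's exact / Benjamini–Hochberg term
   over-representation (significance: adjusted p < 0.01, odds ratio
   > 1).
5. **Synthetic cohorts.** A seeded generator for every input — catalog
   with toy gene models, per-read observations under Poisson depth
   (mean 17.5) and undercount-biased noise, expression matrices with a
   planted tissue preference — with ground truth emitted, so every
   claim above is testable by recovery.

Coordinates are 0-based half-open (BED) everywhere; all I/O is TSV with
`NA` for missing; gzip is transparent by extension.

## Worked example

Simulate a 300-locus, 193-sample cohort with known per-locus true
variability, genotype it, and score it:

```r
library(strvar)
sim    <- simulate_catalog(n_loci = 300, n_genes = 40, seed = 7)
models <- simulate_locus_models(sim$catalog, seed = 8)   # sigma_true ~ U(0,4)
cohort <- simulate_cohort(sim$catalog, models, n_samples = 193, seed = 9)

g   <- build_genotype_matrix(cohort$reads, sim$catalog)  # 300 x 193, 0.36% NA
rec <- score_variability(g)
rec[1:4, c("locus_id", "n_total", "n_used", "p5", "p95", "rdi", "nrdi", "tier")]
#>    locus_id n_total n_used    p5   p95      rdi      nrdi  tier
#> 1: STR00001     193    189    12    18 1.505847 0.3812709  lSTR
#> 2: STR00002     193    187     9    17 2.054172 0.5284281  mSTR
#> 3: STR00003     192    180    18    31 3.256428 0.8862876 vhSTR
#> 4: STR00004     193    182    12    22 2.590990 0.6789298  hSTR
```

Each row: samples genotyped (`n_total`), samples kept inside the
`[p5, p95]` normal range (`n_used`), the range itself, the RDI in repeat
units, its rank-normalized score, and the tier. STR00003's cohort spans
repeats 18–31 even after trimming — a very highly variable locus.

The recovered ordering tracks the simulator's truth, and the most
variable planted loci land where they should:

```r
sigma <- models$sigma_true[match(rec$locus_id, models$locus_id)]
cor(rec$rdi, sigma, method = "spearman", use = "complete.obs")
#> [1] 0.7637  # >= 0.8 at the default 500-locus scale

top <- models$locus_id[order(-models$sigma_true)][1:30]
summarize_subset(rec, top)$tier_proportions
#> [1] 0.0 0.0 0.0 0.2 0.8   # vlSTR..vhSTR; uniform would be 0.2 each

normal_range(g[1, ], "two_sided")
#>  low high
#>   12   18
```

The same flows are available from the command line
(`exec/strvar` in the installed package):

```sh
strvar simulate --n-loci 500 --n-samples 193 --seed 7 --outdir sim/
strvar genotype --reads sim/reads.tsv --catalog sim/catalog.bed --out genotypes.tsv
strvar score    --genotypes genotypes.tsv --out variability.tsv
strvar report   --config run.json        # full chain + manifest.json
```

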