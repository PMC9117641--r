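---
title: "Methods: scoring STR variability from long-read repeat counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring STR variability from long-read repeat counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strvar)
```

## The problem

Short tandem repeats (STRs) — tandem arrays of 3–6 bp motifs — are among
the most mutable elements in the human genome. Which loci are *variable*
in a healthy population is the key prior for interpreting an observed
expansion: a repeat count far outside a locus's normal population range is
a candidate pathogenic allele, while the same count at a hypervariable
locus is unremarkable. Long-read sequencing spans whole repeat tracts, so
a long-read repeat caller can emit a repeat count *per read* at every
cataloged locus in every sample. `strvar` starts from exactly that
read-level table and produces population-scale variability statistics.

## Genotyping: the estimated repeat count (ERC)

At one locus in one sample, the per-read counts are sorted in decreasing
order and the value at 1-based position $\lceil 0.25\,N \rceil$ is the
sample's genotype (ERC). Samples with fewer than 8 reads at a locus are
not genotyped.

Why a top-quartile order statistic rather than the median? Long-read
repeat miscounts are *undercount-biased*: truncated traversals of the
tract, clipped alignments and error-compressed homopolymer-like stretches
all shorten the apparent repeat, while spurious lengthening is rarer. A
high-rank statistic tolerates up to 75% of reads undercalling; the median
breaks as soon as half do.

Two conventions here are deliberate choices, locked by oracle tests
because the rule's prose admits several readings:

* the index is $\lceil 0.25 N\rceil$ on the descending sort (always an
  observed read value; never interpolates);
* one ERC per individual — no diploid allele splitting. All downstream
  statistics consume a single value per sample, and peak calling for
  allele separation is out of scope.

Reads with repeat count 0 still count toward coverage: there is no
sub-count filter, and a read reporting 0 repeats is an observation, not a
failure.

## The repeat dynamic index (RDI)

Per locus, the cohort's ERCs are trimmed to a *normal repeat range* and
their dispersion is scored:

1. **Trim.** Nearest-rank percentiles on the ascending sort of the $n$
   ERCs: lower bound at index $\max(1, \lceil 0.05 n\rceil)$, upper bound
   at index $\lceil 0.95 n \rceil$, except that when $0.95\,n$ is not an
   integer the upper index is capped at $n-1$, so a lone maximum outlier
   is excluded rather than becoming the bound itself. Trimming is
   value-based and inclusive: every ERC $v$ with $p_5 \le v \le p_{95}$
   is kept, so heavy ties at a bound are retained. Products within
   $10^{-9}$ of an integer are snapped to it ($0.95 \times 20$ must be
   19, not 20, despite binary floating point).
2. **Score.** RDI is the *population* standard deviation of the kept
   values $R$:
   $$\mathrm{RDI} = \sqrt{\frac{\sum (R - \bar R)^2}{N}},$$
   with divisor $N$ (the number of kept values), not $N-1$ — verbatim
   fidelity to the defining formula rather than the unbiased estimator.

The source prose for the trimming step is internally contradictory
(removing counts "above the fifth percentile or low 95th percentile"
would remove nearly everything); the two-sided keep-$[p_5, p_{95}]$
reading is implemented, matching the companion phrase "between the
maximum fifth percentile value and 95th percentile value".

A locus is scored only when non-missing ERCs cover at least
`min_fraction` (default 0.8) of the cohort and at least 2 samples. The
original analysis always had all 193 values and states no missing-data
rule; the fraction is configurable.

## nRDI and variability tiers

RDI scales with repeat-count units, so loci are compared on ranks. With
$L$ scored loci and ascending midranks $r_i$ (ties share their average
rank),
$$\mathrm{nRDI}_i = \frac{r_i - 1}{L - 1} \in [0, 1].$$
Whether the normalization is $(r-1)/(L-1)$, $r/L$, or an empirical CDF is
not stated in the source; $(r-1)/(L-1)$ is chosen so the extremes map
exactly to 0 and 1, and midranks make it order-independent and
deterministic under ties.

Tiers are the five 0.2-wide nRDI bins — vlSTR, lSTR, mSTR, hSTR, vhSTR —
with internal boundaries left-closed and 1.0 belonging to vhSTR. By
construction the full scored set spreads uniformly: with distinct RDIs,
each tier holds $L/5 \pm 1$ loci and each decile $L/10 \pm 1$. That
uniformity is the control against which subset profiles (disease loci,
expression-associated loci, motif-size and region strata) are read: any
excess of a subset in the upper tiers is signal, not normalization
artifact.

## Catalog conventions

* Coordinates are 0-based half-open (BED) in every file and function.
* The canonical repeat unit is the lexicographic minimum over all cyclic
  rotations of the motif and of its reverse complement, so CAG, AGC,
  GCA, CTG, TGC and GCT share the representative AGC. Plain reversal is
  *not* in the closure (GTC is not CAG-class); the one published listing
  that includes it is treated as a typographical slip, and equivalence
  is kept strictly group-generated.
* Gene assignment: the gene whose body overlaps the locus (distance 0),
  else minimal gap within 10 kb; gap ties break lexicographically by
  gene id for determinism. Unassigned iff no gene within 10 kb.
* Region classes follow the priority exonic > UTR > intronic > flank.
  The intronic proximal/distal split ("within 1 kb of the nearby gene")
  is ambiguous in the source; it is interpreted as distance from the
  locus to the nearest exon boundary of the assigned gene, which is the
  reading under which proximal/distal is a property of the intron
  position rather than of the gene extent.
* Catalog intersection pairs loci with intersecting intervals and equal
  canonical units, greedily by largest overlap (ties: smallest start,
  then ids); each locus joins at most one pair.

## Expression profiling and enrichment

Cross-tissue expression levels are not directly comparable, so each
tissue column of the genes × tissues matrix is replaced by ascending
midranks scaled to $[0,1]$ via $(r-1)/(G-1)$. The transform is idempotent
— the source's double phrasing ("the rank of the normalized values") is
collapsed to a single rank transform, since ranking ranks is a no-op —
and invariant under any strictly monotone distortion of a column.

A gene set's tissue profile is the per-tissue mean normalized expression
of its members; 0.5 is the no-preference baseline. Per-tissue
significance is operationalized as a two-sided Fisher's exact test on
(in set / out of set) × (above / below the within-tissue median of
normalized expression) — the figure-style per-tissue test is not
described in the source, and this median-threshold construction is a
flagged interpretation, documented rather than hidden.

Term over-representation uses the standard 2×2 Fisher's exact test per
term over a user-supplied universe, two-sided (the source names the test
but not its sidedness), with Benjamini–Hochberg adjustment across all
tested terms; a call additionally requires odds ratio > 1 so that
depleted terms are never reported as "enriched". Significance defaults
to adjusted $p < 0.01$. The universe is intersected with each term's
membership to prevent silent universe inflation. `stats::fisher.test`
and `stats::p.adjust` supply the machinery; the test suite checks both
against an independent hypergeometric-tail oracle and hand step-up
arithmetic over exhaustive small tables.

## The synthetic cohort: a stated world

The generator emulates the *shape* of a long-read STR cohort, with
defaults fixed once to the descriptors of a realistic population-scale
dataset, not tuned to any test outcome:

* 193 samples; Poisson read depth with mean 17.5;
* per-locus true repeat counts: discretized normals floored at 1, median
  size 8–25, between-sample SD $\sigma \sim U(0, 4)$; 10% of loci get a
  second mode (offset 5–15, weight 0.2–0.5), mimicking the single- and
  multi-peak population distributions seen at disease loci;
* read-level noise: each read perturbed with probability 0.10 by
  $1 + \mathrm{Geom}(0.5)$ repeat units, downward with probability 0.8
  (the undercount bias), clamped at 0;
* toy gene models with exons and UTR intervals so that every region
  class is populated; motif lengths 3–6 with tri/tetra dominating
  (~70%); motifs are primitive (never a repetition of a shorter unit);
* expression matrices: log-normal baseline, with a designated gene set
  shifted in one tissue by a chosen number of within-tissue SDs (1.5 by
  default; 0 gives a null matrix).

Every generator is a pure function of (parameters, seed); reruns are
asserted byte-identical on written files.

What the simulator does **not** emulate: base-level sequence, alignment
and mapping bias, GC-dependent miscount structure, linkage between
nearby loci, allelic (diploid) structure, and population substructure. A
green recovery test therefore establishes that the pipeline recovers the
variability ordering *under this noise family* — not that it would on
any particular real cohort.

## What the recovery tests establish

With the defaults above, the pipeline's RDI recovers the planted
$\sigma$ ordering at Spearman $\rho \ge 0.8$ over 500 loci, the
top-decile-$\sigma$ loci land in vhSTR at ≥ 3× the uniform rate, and two
noise regimes (error 0.10 vs 0.02) genotyped independently from one
truth agree at Pearson $r > 0.99$ over ~96,000 shared cells.

One documented negative result: at the default noise the ERC does *not*
beat the per-sample median read count in mean absolute error — both are
nearly exact (MAE ~$2\times10^{-4}$ vs ~$2\times10^{-5}$ repeat units),
because a 10% error rate almost never pushes 50% of a sample's reads
down (which is what it takes to move the median), while the 2% upward
tail occasionally crosses the ERC's 25% rank, especially at the 8-read
coverage floor where the rank index is 2. The corresponding acceptance
test is kept as specified and fails honestly. Under heavier undercount
regimes (error 0.4, bias 0.9) the expected ordering appears and is
asserted green in the unit suite: the top-quartile rule is insurance
against severe undercalling, at the price of a slightly fatter upward
error tail when noise is mild.

## Numerical and degenerate-input choices

* Percentile index products are snapped to integers within $10^{-9}$
  before `ceiling`, preventing binary-fraction misindexing.
* `trim_counts` needs ≥ 2 values; `compute_rdi` needs ≥ 1 kept value;
  rank normalization needs ≥ 2 loci; all error explicitly rather than
  returning NA silently.
* All-equal ERC vectors trim to themselves and score RDI 0.
* Correlation (concordance) errors on < 2 shared cells or zero variance
  rather than returning NaN.
* Missing genotypes are `NA` in memory and `"NA"` in files, distinct
  from 0 (a genotyped zero-repeat allele).
* Config files are JSON; the environment pins no YAML parser, and the
  config surface is flat key–value, which JSON covers.

## Limitations

Beyond the simulator gaps above: the pipeline genotypes one ERC per
sample, so loci with strongly heterozygous repeat lengths fold both
alleles into one order statistic; pathogenicity calling against clinical
thresholds, expansion-outlier detection, and catalog construction from
annotation databases are out of scope; and enrichment is generic over
user-supplied term tables — it does not fetch GO/KEGG.
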