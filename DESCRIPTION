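Package: strvar
Title: Population-Scale Short Tandem Repeat Variability Profiling
Version: 1.0.0
Authors@R:
    person("strvar", "developers", email = "strvar@example.org",
           role = c("aut", "cre"))
Description: Tools for profiling short tandem repeat (STR) variability in
    long-read sequencing cohorts. Converts per-read repeat counts into
    per-sample estimated repeat counts (ERC) with a coverage filter, scores
    per-locus variability with the repeat dynamic index (RDI, a trimmed
    population standard deviation), rank-normalizes RDI into five
    variability tiers, profiles locus subsets (disease-associated and
    expression-associated STRs, motif-size and genomic-region strata),
    rank-normalizes tissue expression matrices to assess tissue preference
    of STR-related gene sets, and runs Fisher/Benjamini-Hochberg gene-set
    over-representation. A seeded synthetic-cohort generator emulates
    long-read repeat-caller output (Poisson depth, undercount-biased read
    noise) with ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
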