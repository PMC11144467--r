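Package: mrtarget
Title: Drug-Target Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("mrtarget", "developers", email = "mrtarget@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for two-sample drug-target Mendelian
    randomization from GWAS summary statistics: cis-instrument selection
    with greedy LD pruning, allele harmonization, instrument-strength
    diagnostics (per-SNP and combined F and R-squared), causal-effect
    estimation by inverse-variance weighting with MR-Egger and
    weighted-median sensitivity analyses, Bayesian colocalization via
    per-variant approximate Bayes factors, and Benjamini-Hochberg false
    discovery rate control. Includes a synthetic two-sample GWAS
    summary-statistics generator with known ground truth (causal effect,
    pleiotropy, LD blocks) so the whole workflow runs without external
    data, and a command-line interface for scripted use.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
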