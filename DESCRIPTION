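Package: admixpgs
Title: Ancestry-Interaction Models and Partial Polygenic Scores in
    Admixed Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of gene-by-ancestry interaction
    models in two-way admixed populations. Generates synthetic admixed
    cohorts (global ancestry, local-ancestry haplotype mosaics,
    ancestry-specific allele frequencies, causal-tagging variant pairs
    with ancestry-specific linkage disequilibrium), simulates continuous
    phenotypes under local- and global-ancestry interaction models,
    computes total and partial polygenic scores and their predictive
    accuracy, and evaluates closed-form predictions for local-ancestry
    average-effect correlations and expected polygenic-score performance.
    Includes Monte Carlo experiment drivers comparing simulation to
    theory and a Wilcoxon rank-sum grid for model distinguishability.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
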