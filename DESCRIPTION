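Package: pcdscreen
Title: Prevalence Estimation and Newborn Screening Algorithms for
    Primary Carnitine Deficiency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the birth prevalence of primary carnitine
    deficiency (and other autosomal-recessive disorders) from carrier counts
    and allele frequencies, using Hardy-Weinberg carrier-frequency,
    sex-stratified permutation-combination, and Beta-posterior Bayesian
    estimators with credible intervals. Also provides curated
    pathogenic-variant catalog summaries, cross-population allele-frequency
    comparison with false-discovery-rate control, genotype-phenotype
    association screens based on exact 2x2 tests, high-frequency variant
    panel design with coverage metrics, a two-tier tandem-mass-spectrometry
    plus gene-panel newborn-screening decision algorithm, and a seeded
    synthetic neonatal cohort generator for validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
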