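Package: regulomeqtl
Title: Integrated Genetic and Epigenetic Mapping of Cis-Regulatory Effects on Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for studying how genetic variants and DNA
    methylation shape tissue gene expression. Provides fetal-versus-adult
    differential methylation and expression testing with dual effect-size and
    FDR thresholds, CpG-island context contingency analysis, rank-based
    cis-eQTL and cis-meQTL mapping with weighted-Z meta-analysis across
    cohorts and permutation-based false discovery rate control,
    expression-methylation (eQTM) association with permutation p-values,
    nested-linear-model partitioning of expression variance into SNP and CpG
    contributions, cross-tissue sharing and allelic-direction concordance
    reports, and matched-probe enrichment. A fully seeded multi-cohort,
    multi-tissue simulator with a planted-effect truth table supports power
    studies and calibration checks without any external data.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
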