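Package: hlaRisk
Title: Case-Control and Family-Based Analysis of HLA Haplotype Risk and
    Interaction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for genetic-epidemiological analysis of HLA class II
    haplotype and genotype risk in case-control and trio-family designs.
    Implements chromosome-level haplotypic and individual-level genotypic
    odds ratios with Woolf confidence intervals and Bonferroni correction,
    the sequential relative predispositional effect (RPE) procedure,
    stratified transmission-disequilibrium analysis of the haplotype
    inherited from the parent not carrying a risk haplotype, and a
    log-additivity (alpha) statistic quantifying deviation of observed
    genotypic odds ratios from the product of the haplotypic ones. A seeded
    simulator of haplotype pools, case-control cohorts and ascertained trio
    families with configurable relative risks and interaction effects makes
    every stage testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
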