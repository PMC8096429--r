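Package: longwgs
Title: Case-Control Whole-Genome Analysis for Extreme-Longevity Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end toolkit for two-group whole-genome sequencing
    studies of extreme human longevity. Implements cohort quality control
    (call-rate and heterozygosity filters, windowed LD pruning, principal
    component outlier removal), common-variant association with Fisher's
    method combination across cohorts and permutation-based multiplicity
    adjustment, haplotype-cluster pseudomarker association, private and
    rare-variant collapsing burden analysis, a clonal-hematopoiesis
    somatic-mutation caller over a seven-gene panel with cross-group
    coverage quantile normalization and exact binomial germline exclusion,
    and weighted-allele polygenic risk scores with linkage-disequilibrium
    proxy substitution. A synthetic cohort generator with planted ground
    truth makes every stage testable without access-restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    car
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
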