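Package: bimr
Title: Bidirectional Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Artifact", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A pipeline for bidirectional two-sample Mendelian randomization
    (MR) from GWAS summary statistics: reading and validating per-SNP
    association tables, significance filtering and greedy LD pruning of
    genetic instruments with per-SNP F statistics, allele harmonization
    across studies (including palindromic-SNP resolution by allele
    frequency), causal-effect estimation with the Wald ratio, inverse
    variance weighted (IVW), MR-Egger and weighted-median estimators, the
    Cochran Q heterogeneity test and the MR-PRESSO outlier test, family-wise
    Bonferroni correction across a set of bidirectional analyses, and a
    synthetic two-sample GWAS generator with known ground truth for offline
    validation of the whole pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table
Suggests: testthat (>= 3.0.0), withr, jsonlite, optparse
Config/testthat/edition: 3
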