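Package: mrbiome
Title: Bidirectional Two-Sample Mendelian Randomization for Gut Microbiota
    and Pancreatitis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A tested pipeline for bidirectional two-sample Mendelian
    randomization between gut-microbiome taxon abundances and pancreatitis
    phenotypes using GWAS summary statistics. Implements instrument
    selection (p-value screen, LD clumping, confounder blacklist,
    F-statistic filtering), effect-allele harmonization with palindromic
    SNP removal, five causal estimators (Wald ratio, inverse-variance
    weighted, MR-Egger, weighted median, weighted mode) plus MR-PRESSO
    outlier detection, heterogeneity and pleiotropy diagnostics
    (Cochran's Q, Egger intercept, leave-one-out), and per-taxonomic-level
    Bonferroni and Benjamini-Hochberg multiplicity control. Includes a
    summary-level GWAS simulator so every stage is testable without any
    data download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
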