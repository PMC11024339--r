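Package: bidirMR
Title: Bi-Directional Two-Sample Mendelian Randomization on GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end, reproducible pipeline for bi-directional two-sample
    Mendelian randomization (MR) between sets of exposure and outcome traits
    using GWAS summary statistics. Implements genome-wide-significant instrument
    selection with F-statistic and confounder screening, greedy LD clumping,
    allele harmonization with palindromic and strand-mismatch handling, five
    causal estimators (inverse-variance weighted with fixed/random model
    selection, MR-Egger, weighted median, penalized weighted median, and
    profile maximum likelihood), Cochran's Q and Egger-intercept diagnostics,
    a Monte-Carlo MR-PRESSO global and per-SNP outlier test with iterative
    removal, and Bonferroni-gated reporting over the full exposure-by-outcome
    grid in both directions. A synthetic GWAS summary-statistic generator with
    known causal effects, pleiotropy models, LD blocks, palindromic alleles,
    and confounder annotations makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
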