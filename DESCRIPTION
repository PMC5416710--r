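Package: telomr
Title: Mendelian Randomization Meta-Analysis of Telomere Length and Cognitive Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a multi-cohort Mendelian randomization (MR) pipeline for
    estimating the causal effect of leukocyte telomere length (qPCR T/S-ratio) on
    cognitive traits. Provides construction of an additive unweighted genetic risk
    score over seven telomere-length loci (with allele harmonization), per-cohort
    standardized linear association models with age-group and sex adjustment and
    APOE e4 stratification, inverse-variance fixed-effect pooling with a
    DerSimonian-Laird random-effects switch under significant Cochran-Q
    heterogeneity, Wald-ratio instrumental-variable estimation with delta-method
    standard errors and instrument F-statistics, observed-versus-causal difference
    Z-tests, and a two-sample inverse-variance-weighted estimator for GWAS summary
    statistics. A synthetic multi-cohort generator with a confounded linear
    structural model makes every stage testable without individual-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr,
    jsonlite
Config/testthat/edition: 3
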