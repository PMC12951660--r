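Package: mrmediate
Title: Two-Sample Mendelian Randomisation with Metabolite Mediation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomisation (MR) mediation
    studies linking gut microbiota, plasma metabolites and a binary disease
    outcome from GWAS summary statistics: instrument selection (p-value
    threshold, greedy LD clumping, F-statistic filter, outcome-association
    exclusion), allele harmonisation with palindromic-SNP handling, the MR
    estimator suite (inverse-variance weighted, MR-Egger, weighted median,
    MR-PRESSO) with Cochran's Q and pleiotropy diagnostics, fixed-effects
    meta-analysis across outcome cohorts with Bonferroni screening, a
    simplified cross-trait LD-score regression, and product-of-coefficients
    mediation with bootstrap confidence intervals. A synthetic-data module
    generates multi-cohort GWAS summary statistics with known causal
    structure so the whole pipeline can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    withr
Suggests:
    testthat (>= 3.0.0),
    metafor,
    jsonlite
Config/testthat/edition: 3
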