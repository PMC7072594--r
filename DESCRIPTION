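Package: stratsurv
Title: Expression-Based Survival Stratification, Differential Expression
    and Gene-Set Enrichment
Version: 0.1.0
Authors@R: person("Maintainer", "Package", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Stratifies patient cohorts by the expression of a single index
    gene using an iteratively optimized log-rank (Mantel-Haenszel) cutpoint,
    tests survival differences between the resulting high/low strata
    (Kaplan-Meier, Mantel-Haenszel, Gehan-Wilcoxon, univariate Cox), performs
    stratified differential expression with Benjamini-Hochberg correction and
    a fold-regulation rule, intersects regulated genes across studies, and
    scores gene-set enrichment with the Fisher exact test and its conservative
    EASE variant.  A synthetic multi-study data generator with planted effects
    makes every stage testable without cohort downloads.  Also includes
    immunohistochemistry H-score utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    tools
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr
Config/testthat/edition: 3
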