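Package: pathmeta
Title: Pathway-Level Survival Prognosis, Meta Differential Co-Expression and
    Paired Differential Expression for Multi-Cohort Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Pathway-centric analysis of multi-cohort bulk expression data.
    Scores each pathway in each cohort with a composite gene expression score
    (a logistic transform of a Cox-coefficient-weighted sum of standardized
    log expression, median-centered), assesses its prognostic value with a
    full-refit permutation test and Benjamini-Hochberg adjustment, and draws
    Kaplan-Meier curves for the median score split. Tests tumor-versus-normal
    co-expression rewiring per pathway with a Gene Sets Net Correlations
    Analysis (GSNCA) statistic, converts permutation p-values to logit effect
    sizes with bootstrap standard errors, and pools them across cohorts with a
    DerSimonian-Laird random-effects model, yielding a back-transformed meta
    p-value and forest tables. Tests paired tumor-versus-normal differential
    expression of patient-wise pathway means. Ships GMT gene-set curation
    (same-name merging and pairwise overlap enforcement), cohort loaders, a
    synthetic multi-cancer cohort generator with known ground truth, and an
    end-to-end pipeline driver.
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
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    metafor,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
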