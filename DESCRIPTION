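Package: twinmeth
Title: Twin-Based Epigenome-Wide Association and Variance-Component Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for epigenome-wide association studies (EWAS) of DNA
    methylation in twin cohorts. Provides family-aware per-CpG generalized
    least squares with empirical-Bayes variance moderation, dual-platform
    meta-analysis of partial-correlation effect sizes with heterogeneity
    triage, full-information maximum-likelihood univariate twin models
    (ACE/ADE/AE/CE/DE/E) with profile-likelihood confidence intervals and
    likelihood-based model selection, five-group sex-limitation models for
    quantitative and qualitative sex differences, within/between-pair
    decomposition of exposure effects in discordant twin pairs, and
    correlation of methylation quantitative trait locus (meQTL) counts with
    heritability. Includes a seeded synthetic twin-cohort generator with
    configurable additive-genetic, shared- and unique-environment variance
    fractions and known phenotype-methylation linkage, so the whole pipeline
    is testable against ground truth. Phenotype scoring covers pubertal
    development scale (PDS) questionnaire items and censored pubertal age.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4
Suggests:
    testthat (>= 3.0.0),
    limma,
    metafor,
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
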