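Package: rapasens
Title: Quantitative Genetics and Metabolomics of Rapamycin Sensitivity in
    Inbred Line Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for mapping natural genetic variation in drug
    sensitivity across panels of fully inbred lines, built around a
    developmental-delay screen in Drosophila. Turns per-vial pupation
    records into per-line delay phenotypes with pooled standard errors,
    estimates SNP heritability by gBLUP/REML on a genomic relationship
    matrix with bootstrap and permutation resampling, tests single markers
    and marker sets (genes, genes +/- 1 kb, pathways) with the covariance
    association test and Storey q-values, and analyses larval metabolomes:
    per-sample normalisation, empirical-Bayes batch correction, PCA,
    per-metabolite mixed models, and projection of study samples onto a
    starvation-derived principal-component axis with a saturating
    time-trajectory fit. A synthetic-data module emulates every input so
    the full pipeline runs and validates without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    minpack.lm,
    sva,
    fgsea,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    car,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
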