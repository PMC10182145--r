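Package: otoscan
Title: Survival GWAS, Gene-Set Enrichment and Risk Modelling for
    Treatment-Induced Hearing Loss
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for time-to-event genome-wide association analysis of
    chemoradiation-induced hearing loss in cancer cohorts: variant-level
    quality control (call rate, minor allele frequency, Hardy-Weinberg exact
    test, imputation INFO), genotype principal components, per-SNP additive
    Cox proportional-hazards scans with clinical and ancestry covariates,
    genomic-inflation diagnostics, permutation-based gene-set enrichment
    against hereditary-deafness gene regions, clinical Cox modelling with
    ROC-derived cutoffs, and a combined genetic plus clinical risk score with
    train/test validation using censoring-aware time-dependent AUC. Includes
    a synthetic-data generator emulating the statistical structure of such a
    cohort so every stage is testable without restricted individual-level
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    survival,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    vcfR,
    rtracklayer,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
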