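Package: lipidvc
Title: Pedigree Variance Components and Mixed-Model GWAS for Lipidomic
    Traits in Founder Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative-genetic analysis of lipid species measured in
    multi-generation founder-population pedigrees. Computes pedigree
    kinship and dominance covariance matrices, SNP genetic-relationship
    matrices and data-derived lipidome-class covariance matrices, and
    partitions phenotypic variance over arbitrary sets of such matrices
    by average-information REML with likelihood-ratio model comparison
    and greedy sequential component selection. Includes covariate
    residualization with rank-based inverse normal transformation,
    bivariate mixed-model genetic correlation with out-of-range masking,
    two-stage linear mixed-model association scans with sequential
    conditional analysis, principal-component-based multiple-testing
    thresholds, analytic replication-exclusion power, and a seeded
    gene-dropping simulator of drifted founder variants and
    class-structured lipidome phenotypes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    knitr
Config/testthat/edition: 3
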