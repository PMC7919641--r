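Package: pgxpredict
Title: Evolution-Aware Prediction of Pharmacogenetic Variants from Global
    Population Variation
Version: 0.1.0
Authors@R:
    person("Coriell", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested, reusable pipeline for in silico prediction of
    pharmacogenetic (PGx) missense variants from population-genetic and
    protein-feature evidence. Provides permutation-based enrichment tests of
    pharmacogenes among adaptive-signature loci, assembly of a 14-variable
    model matrix from evolutionary statistics and UniProt feature tracks,
    SMOTE class balancing inside repeated stratified cross-validation,
    three tree-ensemble learners (random forest, LogitBoost, gradient
    boosted trees) with sensitivity-weighted model selection, and downstream
    allele-frequency and annotation-trend reports across the 26 reference
    population samples. A synthetic-data generator with a Balding-Nichols
    allele-frequency model makes every stage testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    SummarizedExperiment,
    VariantAnnotation
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
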