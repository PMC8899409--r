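Package: odorDB
Title: Curation and Meta-Analysis of Insect Odorant-Response Databases
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for standardizing heterogeneous behavioral and
    electrophysiological odorant-response measurements (preference indices,
    concentration unit conversion, electroantennogram normalization,
    background subtraction, odorant synonym resolution) into a uniform
    record schema, and for pattern discovery across the standardized
    records: Gaussian tuning of odorant-receptor responses to
    physicochemical properties with a shuffle-based permutation null,
    feedforward neural-network prediction of receptor responses from
    molecular descriptors with a shuffled-response control, cross-technique
    sensitivity cross-tabulation, behavioral assay-category comparison,
    preference-oviposition and cross-species correlations, and
    concentration-dependence statistics. Includes a seeded synthetic
    database generator with planted, recoverable effects for closed-loop
    validation of every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'signrank.R'
    'conditions.R'
    'comparative.R'
    'curation.R'
    'descriptor.R'
    'mlp.R'
    'odorDB-package.R'
    'synthetic.R'
    'standardize.R'
    'tuning.R'
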