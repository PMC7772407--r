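Package: lncrules
Title: Interpretable Classification of Cancer-Related lncRNAs from
    Co-Expression Enrichment Profiles
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Guilt-by-association pipeline for discriminating cancer-related
    long non-coding RNAs. Each lncRNA is encoded by -log10 hypergeometric
    upper-tail enrichment scores of its co-expressed gene set against GO and
    KEGG annotation terms; features are ranked by minimum-redundancy
    maximum-relevance (mRMR) mutual information; a CART decision tree
    evaluated by stratified 10-fold cross-validation (Matthews correlation
    coefficient) drives incremental feature selection, with SMOTE
    oversampling of the rare positive class; the selected tree is rendered
    as human-readable decision rules. Includes a synthetic-data generator
    with planted discriminative terms so the full pipeline is testable
    without external annotation downloads.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
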