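Package: fpresample
Title: Resampling Strategies for Imbalanced Binary Fingerprint Datasets
Version: 0.1.0
Authors@R:
    person("fpresample", "maintainers", email = "maintainers@fpresample.org",
           role = c("aut", "cre"))
Description: Tools for balancing imbalanced binary chemical datasets before
    classification. Implements eight resampling strategies for binary
    molecular fingerprints (MACCS, Morgan): random and
    most-common-feature (MCF) guided under- and over-sampling,
    Tanimoto-cost k-medoids under-sampling, and binary SMOTE variants
    using Tanimoto or Value Difference Metric neighborhoods with 2-of-3
    majority-vote bit synthesis. Includes a seeded random-forest
    classifier for binary features, a stratified cross-validation and
    external-validation harness reporting accuracy, sensitivity,
    specificity, F-measure and ROC-AUC, a synthetic imbalanced
    fingerprint generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: Python (>= 3.8) with RDKit, required only for
    computing fingerprints from SMILES/SDF input.
Config/testthat/edition: 3
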