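Package: ocscreen
Title: One-Class Screening of Pi-Pi Co-Crystal Co-Formers
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A one-class classification workflow for ranking candidate
    molecular pairs by their likelihood of forming weakly bound pi-pi
    stacked co-crystals. Covers labelled-dataset assembly and filtering
    from multi-component SMILES, complementarity-driven descriptor
    selection and min-max scaling, an ensemble of eight traditional
    one-class detectors (Gaussian mixture density, local outlier factor,
    kNN distance, isolation forest, one-class SVM, histogram-based
    outlier score, cluster-based LOF and feature-bagged LOF), a
    permutation-invariant deep hypersphere (Deep SVDD style) model with
    autoencoder pretraining, Shapley-value interpretability,
    stoichiometry (1:1 vs other) classification with SMOTE balancing and
    gradient-boosted trees, and multi-objective Pareto candidate
    selection. Seeded synthetic-fixture generators make the whole
    pipeline testable without any proprietary database or descriptor
    software.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
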