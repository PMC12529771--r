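Package: latentmol
Title: Sequence-to-Sequence SMILES Autoencoder Descriptors and Latent-Space Drug-Discovery Pipelines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A recurrent sequence-to-sequence autoencoder that maps SMILES
    strings to fixed-length continuous latent descriptors and back, together
    with the latent-space operations built on those descriptors: Euclidean
    similarity search, controlled perturbation, linear and weighted
    interpolation, Gaussian semirandom sampling, and PCA-derived descriptor
    directions. Downstream pipelines cover protonation-state ranking from
    state penalties, ADMET endpoint heads with class-imbalance resampling
    (random undersampling and SMOTE), and an iterative ligand-based
    virtual-screening benchmark reporting ROC-AUC and enrichment factors.
    Includes curation of raw SMILES corpora (organic filter, salt and
    stereochemistry stripping, property bounds), character-level
    tokenization with two-character halogen tokens, and synthetic-data
    generators that make every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
SystemRequirements: Python (>= 3.9) with the RDKit package on the PATH as
    'python' (used for SMILES parsing, canonicalization, descriptor and
    fingerprint computation).
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
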