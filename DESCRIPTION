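Package: ldapls
Title: LDA-PLS and ex-LDA-PLS Supervised Dimension Reduction for Two-Class
    Spectral Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-class linear discriminant analysis (LDA) whose projection
    direction is iteratively corrected by NIPALS partial least squares (PLS)
    regression (LDA-PLS), plus a lambda-blended direction between the LDA and
    LDA-PLS solutions (ex-LDA-PLS) with grid search of lambda on a held-out
    half of the training set. Includes from-scratch SVD-based LDA and
    NIPALS-PLS primitives, seeded generators for a two-dimensional toy set and
    high-dimensional collinear spectra-like data, and a comparative evaluation
    protocol (Gaussian linear classifier on projected scores, G-Mean and
    F-Value, repeated stratified 7:3 splits, 10-fold cross-validation over the
    number of latent variables, PCA and PLS-LDA baselines, component sweeps).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
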