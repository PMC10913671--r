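Package: saxsshape
Title: Simulation and Machine-Learning Classification of Nanoparticle
    SAXS Form Factors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulates laboratory-realistic small-angle X-ray scattering
    (SAXS) curves for nine classical nanoparticle form factors (spheres,
    cylinders, prolate and oblate ellipsoids and their core-shell
    counterparts), including instrument beam smearing and Poisson counting
    noise for two benchtop device configurations.  Provides the SAXS-specific
    preprocessing operators (thresholding, logarithm, standardization,
    Porod-invariant normalization, logarithmic q-resampling), latent-space
    representations (Guinier/Kratky invariant features, PCA, a supervised 1D
    convolutional encoder implemented in compiled code), and classifiers
    (KNN, random forest, gradient boosting, softmax layer) together with
    cross-validation, cross-configuration transfer and real-data scoring
    protocols for automated form-factor model selection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    pracma,
    jsonlite,
    yaml,
    randomForest,
    xgboost,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
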