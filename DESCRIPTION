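Package: irsabp
Title: Chaos-Enhanced Reptile Search Optimization of Backpropagation
    Networks for Binary Clinical Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains small feed-forward neural networks for binary clinical
    classification by seeding backpropagation with weights found by an
    improved Reptile Search Algorithm (IRSA): cubic chaotic-map population
    initialization with elite opposition-based learning, golden-ratio
    blended encirclement updates, a nonlinear decreasing hunting factor,
    and a sigmoid-stabilized reduction function. Includes the baseline
    Reptile Search Algorithm as a comparison optimizer, a Pima-style
    synthetic tabular data generator, a leak-aware preprocessing pipeline
    (zero-as-missing mean imputation, min-max normalization, stratified
    splitting, SMOTE oversampling), and confusion-matrix / ROC / AUC
    evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
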