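Package: stressfl
Title: Individual, Centralized, and Federated Logistic Regression for
    Smartwatch Stress Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulation and analysis toolkit comparing three learning
    topologies -- individual (one model per wearer), centralized (one pooled
    model), and federated (FedAvg) -- for binary stress detection from
    smartwatch physiology.  Provides a seeded generator of synthetic
    multimodal recordings (skin temperature, 3-axis acceleration,
    electrodermal activity, blood volume pulse) with per-second condition
    labels and non-IID participant heterogeneity; a 420-column feature
    pipeline (42 derived signals via derivatives and Haar wavelet
    approximations, 10 sliding-window statistics); an L2-regularized
    logistic-regression learner with both Newton batch fitting and
    local-epoch mini-batch SGD; a from-scratch FederatedAveraging
    simulation; and per-participant confusion-matrix evaluation with
    macro-averaged accuracy, precision, recall and F1 reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tibble,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    glmnet,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
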