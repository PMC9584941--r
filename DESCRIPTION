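Package: nodalpet
Title: Node-Level Evaluation of PET/CT Classifiers Against EBUS-TBNA in Stage-III NSCLC
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating PET/CT-based prediction of lymph-node
    involvement at the level of individual sampled nodes, with endobronchial
    ultrasound-guided transbronchial needle aspiration (EBUS-TBNA) as the
    reference test. Provides a synthetic node-level cohort generator with a
    latent-truth layer and configurable EBUS sensitivity; a case-weighted
    logistic model fitted by iteratively reweighted least squares together
    with tree-ensemble and feed-forward classifier backends; calibration of
    classifier operating points to target sensitivities via case weights and
    probability cut-offs; threefold and nested cross-validation with a
    sensitivity-first inner selection rule; weighted exact McNemar, Fisher
    exact, Kruskal-Wallis, DeLong AUC comparison and per-echelon false
    discovery rate statistics; and closed-form sensitivity/specificity
    algebra for OR-combined diagnostic tests with expected-error arithmetic
    at an assumed prevalence.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    ranger,
    nnet,
    pROC
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
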