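Package: rhinoml
Title: Metaheuristic AutoML for Rhinoplasty Prognosis Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Automated machine learning for prognosis after autologous costal
    cartilage rhinoplasty. A chaotic-map-initialised, Levy-flight-augmented
    population metaheuristic (INPDOA) jointly selects a base learner, a binary
    feature subset and hyperparameters under a dynamically weighted
    cross-validated fitness. Includes a CEC2022-style benchmark suite with a
    multi-algorithm comparison harness, a synthetic cohort generator with
    plantable ground-truth effects, classification and regression metric
    suites with decision-curve analysis, model-agnostic Shapley attribution
    with an exact enumeration oracle, and a clinical-report front end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    e1071,
    glmnet,
    xgboost,
    rpart,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
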