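Package: batchtea
Title: Stochastic Techno-Economic Assessment of Batch API Manufacturing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Monte Carlo techno-economic assessment (TEA) of a batch active
    pharmaceutical ingredient (API) process with machine-learning surrogate
    models. Provides a calibrated batch-process and operating-cost model for an
    API made by quinaldine-hydroquinone condensation, a discounted-cash-flow
    engine (NPV, IRR, and the minimum product selling price as the zero-NPV
    price), a reproducible uniform-sampling scenario generator, a six-model
    multi-output surrogate pipeline with multitask-LASSO feature selection and
    randomized hyperparameter search, and uncertainty analyses (Spearman rank
    correlations, kernel density marginals, SHAP attributions, and a
    cubic-interpolated MPSP(IRR, UPC) feasibility heatmap).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    glmnet,
    xgboost,
    randomForest,
    e1071,
    caret,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
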