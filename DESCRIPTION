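Package: regrselect
Title: Leak-Free Benchmarking and Statistical Selection of Regression Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A benchmarking harness and model-selection toolkit for comparing
    multiple regression learners on tabular (e.g. QSAR descriptor) data.
    Implements repeated 75/25 train/test splits with external cross-validation
    wrapped around internal hyperparameter tuning, a ten-model zoo under one
    fit/tune/predict contract, Y-randomization, and a statistically rigorous
    best-model selection stage: assumption checks (Shapiro-Wilk, Bartlett),
    Friedman omnibus test with the Iman-Davenport extension, post-hoc z
    comparisons against the best-ranked control with Finner-adjusted p-values,
    and contrast estimation based on medians. The legacy windowed R-squared /
    RMSE selection rule is available for side-by-side comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    MASS,
    glmnet,
    randomForest,
    e1071,
    nnet,
    mixOmics,
    caret,
    car,
    yaml,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
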