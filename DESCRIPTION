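Package: prombench
Title: Fuzzy-Weighted PROMETHEE II Ranking of Binary Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Benchmarks binary classifiers (support vector machine, random
    forest, logistic regression, k-nearest neighbour, naive Bayes) under a
    leakage-free preprocessing and stratified cross-validation protocol,
    assembles a mixed quantitative/qualitative decision matrix, and ranks the
    models with a PROMETHEE II outranking procedure using Gaussian preference
    functions and criterion weights obtained by Yager defuzzification of
    triangular fuzzy linguistic importances. Includes a seeded generator of
    two-class Gaussian-mixture tabular data for end-to-end testing, net-flow
    decomposition into per-criterion contributions, and CSV/JSON readers and
    writers for decision matrices, criteria configurations and flow reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    class,
    e1071,
    randomForest,
    pROC,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
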