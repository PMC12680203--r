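Package: mdem
Title: Minimum Displacement in Existing Moment Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Supervised classification of numeric tabular data by the minimum
    displacement in existing moment (MDEM) principle: a test point is assigned
    to the class whose n-th central moment vector is least perturbed, after
    cardinality weighting, by the point's inclusion. Class moments are kept as
    raw powered sums so that training is a single pass over the rows and each
    prediction costs constant time in the training-set size, with optional
    online evolution of the winning class after every prediction. Includes the
    closed-form single-point update of the mean and of arbitrary-order central
    moments, a preprocessing pipeline for clinical tabular data (mean
    imputation, interquartile-range outlier filtering, min-max scaling), k-fold
    and stratified k-fold cross-validation with confusion-matrix metrics, a
    synthetic-data generator with independently controllable per-class mean,
    variance, skewness and tail weight, and CSV/ARFF readers plus a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    foreign,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    class,
    e1071,
    optparse,
    randomForest,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
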