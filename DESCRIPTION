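Package: ducf
Title: User-Based Collaborative Filtering Imputation and Reliability
    Scaling for Clinical Dementia Test Scores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Imputes missing clinical brain-activity test scores (MMSE, GDS,
    CDR, NIQ, FAQ) from MRI morphometrics and demographics by unsupervised
    user-based collaborative filtering: patients are matched by one of five
    similarity weights (Pearson, median-based robust correlation, cosine,
    inverse Manhattan and inverse Euclidean distance) and a missing score is
    predicted as the similarity-weighted average over the best-neighbor-count
    (BNC) most similar patients.  Includes FreeSurfer-style preprocessing
    (hemisphere averaging, keyword selection, reference-volume and min-max
    normalisation), reference imputers (zero, attribute mean, winsorized
    mean, median, low-rank matrix completion), a masking-based evaluation
    harness reporting MAE, MSE, RMSE and R-squared with rank-sum ordering of
    configurations, a two-sigma reliability scale labelling clinical scores
    trusted, moderate or not trusted, and a synthetic cohort generator so
    the whole pipeline is testable without access-controlled data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
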