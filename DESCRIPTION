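Package: nirscog
Title: Permutation Analysis of fNIRS Activity and Cognitive Change in a
    Two-Arm Training Trial
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a two-arm randomized cognitive-training trial with
    dual source-detector (short-separation) fNIRS recordings, preprocesses
    raw shallow/deep total-hemoglobin signals into per-participant baseline
    dorsolateral-prefrontal activity estimates (detrending, zero-phase
    low-pass filtering, short-separation regression, rest-block baseline
    correction, block averaging), and tests whether baseline activity
    predicts cognitive change using Freedman-Lane permutation ANCOVA,
    permutation multiple regression with standardized coefficients,
    Benjamini-Hochberg false-discovery-rate adjustment, and 5-fold
    cross-validated RMSE comparison of left- versus right-hemisphere
    prediction models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
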