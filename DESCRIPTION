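Package: gaitscore
Title: Instrumental Orthopaedic Scores from 3D Gait Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts a 744-feature description of a representative gait
    cycle from joint-angle time series -- spatiotemporal parameters, Perry
    gait-phase parameters, and per-angle movement characteristics including
    normalised angular velocities obtained from degree-five interpolating
    B-splines -- and evaluates instrumental Harris Hip Score and Knee
    Society (knee) Score regression models from them. Also provides the
    hierarchical stepwise regression pipeline (staged predictor entry with
    p-value thresholds, predictor caps, train/test split, tenfold
    cross-validation and regression diagnostics) used to derive such
    instrumental scores, and a synthetic gait simulator for end-to-end and
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lmtest,
    purrr,
    readr,
    rlang,
    splines,
    stats,
    stringr,
    tibble,
    tidyr,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
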