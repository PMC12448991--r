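Package: weightsense
Title: Models of Perceived Weight for Object Pairs and the Size-Weight Illusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for studying heaviness perception in paired-lift
    magnitude-estimation experiments, with the size-weight illusion as the
    central test case. Provides stimulus-set and trial-list construction for
    three-subset cube designs, a synthetic-data generator for
    magnitude-estimation cohorts, the grams-transform / normalisation /
    iterative outlier-removal preprocessing pipeline, a descriptive model of
    perceived weight with a Gaussian weight-difference gate on density terms,
    an efficient-coding Bayesian model of bias in perceived log weight ratio,
    two competing models (a three-sub-prior Bayesian mixture and a
    weight-density cue-combination model), and a common evaluation harness
    with leave-one-out cross-validation across participants.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
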