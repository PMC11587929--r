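Package: rtcump
Title: Response-Time Thresholds and Rapid-Guessing Flags via Cumulative
    Proportion Correct
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates item-level response-time thresholds for detecting
    rapid guessing on dichotomously scored test items using the cumulative
    proportion correct (CUMP) rule, alongside descriptive mean and
    mean-plus-one-SD cutoffs. Flags respondents whose response times deviate
    from the item thresholds on a configurable share of items, renders
    per-person engagement profiles, and ships a two-parameter logistic plus
    lognormal response-time mixture simulator so the whole pipeline can be
    exercised on data with known ground truth. Inputs and outputs are
    comma-delimited person-by-item matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    tools,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
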