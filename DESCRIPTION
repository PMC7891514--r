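Package: persref
Title: Personal Reference Ranges for Longitudinal Laboratory Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation and comparison of intra-individual (personal) reference
    ranges for repeatedly measured clinical laboratory analytes. Implements four
    estimators from a subject's own measurement history: the naive mean +/- 1.96
    SD interval, the reference-change-value (RCV) interval built from analytical
    and within-subject coefficients of variation, the Student-t prediction
    interval for one future observation, and an empirical-Bayes normal-normal
    shrinkage interval driven by between- and within-subject variance components
    estimated from a balanced longitudinal panel. Includes cumulative
    re-estimation of every interval as visits accrue, flagging of new
    observations against the prevailing interval, a synthetic-panel generator
    with the additive subject + visit + noise structure of the underlying mixed
    model, and an end-to-end reporting pipeline comparing all methods against
    conventional population reference ranges.
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
    tools,
    utils,
    yaml
Suggests:
    lme4,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
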