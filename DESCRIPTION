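Package: trialcea
Title: Within-Trial Cost-Effectiveness and Cost-Utility Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for within-trial economic evaluation of a
    three-arm randomized trial of internet-based psychoeducation for bipolar
    disorder, from an Australian health-sector perspective. Covers bottom-up
    microcosting of intervention delivery, pricing of self-reported service
    use, SF-6D utility scoring and QALY computation by the area-under-the-curve
    method, adjusted between-arm mean differences from repeated-measures
    models with unstructured covariance and from identity-link GLMs with
    principled family selection (modified Park test) and link diagnostics,
    paired bootstrap inference on incremental cost-effect pairs with
    reordered-percentile confidence intervals, cost-effectiveness planes and
    acceptability curves, and a predictive-mean-matching imputation bootstrap
    for missing-data sensitivity analysis. Includes a synthetic trial
    generator emulating the design so the full pipeline is testable without
    access to trial data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    nlme,
    jsonlite,
    yaml,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
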