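Package: dualtasksim
Title: Simulation and Analysis of Dynamic Dual-Task Training Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a continuous visuomotor-tracking plus shape-discrimination
    dual-task training experiment end to end: 49-level difficulty ladders with an
    adaptive proportional staircase and regression-based threshold selection,
    synthetic observers with logistic psychometric functions, interference and
    learning parameters, a ten-session pre/training/post protocol with a transfer
    battery (PRP, single response selection, Stroop, attentional blink, go/no-go,
    flanker), dual-task cost and transfer-effect metrics with an a-priori outlier
    exclusion rule, and an inference layer (two-by-two mixed ANOVA with partial
    eta squared, pooled t tests, BIC-approximated Bayes factors composed by
    transitivity). All data are generated by the package; runs are reproducible
    from a single seed.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    lme4,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
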