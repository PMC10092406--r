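Package: weightregain
Title: Weight-Regain Synthesis and Cost-Effectiveness of Behavioural
    Weight Management Programmes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for synthesising intervention-versus-control weight-regain
    trajectories after behavioural weight management programmes and for
    translating them into lifetime health and economic outcomes. Provides
    construction of study-level difference series aligned to programme end,
    three synthesis models (a random-intercept mixed model, a random-effects
    meta-regression, and a Kaplan-Meier time-to-crossing analysis),
    standardised quality-of-life co-analysis, a proportional multi-state
    lifetable engine driven by population impact fractions, cost-effectiveness
    threshold and return-on-investment calculations, Monte Carlo uncertainty
    propagation with tornado decomposition, and synthetic generators for both
    trial corpora and toy epidemiological inputs.
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
    lme4,
    metafor,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
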