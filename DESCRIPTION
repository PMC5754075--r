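Package: gadcea
Title: Cost-Effectiveness Modelling of Cognitive Behavioral Therapy for
    Generalized Anxiety Disorder
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A deterministic Markov cohort model of generalized anxiety
    disorder (GAD) progression and treatment, with a full cost-utility
    layer. Seven GAD-7-derived health states are propagated over 3-month
    cycles for a 100,000-person cohort; intervention strategies (an
    app-delivered mobile CBT program, traditional face-to-face CBT, and
    status quo) modify severity transitions with a linear waning function.
    Discounted costs and quality-adjusted life-years are accumulated from
    societal and payer perspectives, and the package implements one-way
    parameter sweeps, scenario variants and threshold searches for
    deterministic sensitivity analysis, plus a synthetic generator for
    paired GAD-7 pilot screens and an efficacy estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    tibble,
    tidyr,
    readr,
    yaml,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
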