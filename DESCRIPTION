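Package: screencea
Title: Cost-Effectiveness Analysis of Risk-Stratified Breast Cancer Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A Markov cohort state-transition model comparing a polygenic
    risk-tailored breast cancer screening programme against biennial
    mammogram-only screening from a healthcare-system perspective. Provides
    the full decision-analytic pipeline: typed, validated model parameters
    with a bundled Singapore baseline; explicit per-risk-group screening
    schedules; an annual-cycle cohort engine accumulating discounted costs,
    life years and quality-adjusted life years; incremental
    cost-effectiveness ratios with dominance classification; one-way
    (tornado) and probabilistic sensitivity analyses with Gamma/Beta
    parameter distributions and cost-effectiveness acceptability curves;
    percentile-cutoff scenario analysis; a synthetic parameter-set generator
    and an individual-level microsimulation oracle for validating the cohort
    recursion.
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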