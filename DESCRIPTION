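Package: brcacea
Title: Cost-Effectiveness of Population-Based BRCA1/BRCA2 Testing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic Markov cohort model comparing population-based
    BRCA1/BRCA2 genetic testing against clinical-criteria/family-history-based
    testing in women aged 30 years and older. Computes lifetime discounted
    costs, life-years, quality-adjusted life-years and incremental
    cost-effectiveness ratios from payer and societal perspectives, together
    with population impact per million women, one-way (tornado) sensitivity
    analyses, probabilistic sensitivity analysis with cost-effectiveness
    acceptability curves, threshold analyses on testing cost and pathogenic
    variant prevalence, and a grid of scenario analyses (older testing and
    surgery ages, reduced uptake, reduced test sensitivity). Includes a
    synthetic-inputs generator for the age-indexed incidence, life-table,
    survival and productivity inputs the model requires, with documented CSV
    schemas so registry data can be substituted.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ggplot2,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
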