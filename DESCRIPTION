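Package: cdsthru
Title: Claims-Based Stratification of Vedolizumab Response Probability and
    Healthcare Resource Utilization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scores patients with Crohn's disease from longitudinal
    administrative-claims tables using the 5-variable and modified 3-variable
    vedolizumab clinical decision support tools (CDSTs), builds eligible
    treatment cohorts (index-date and continuous-enrollment rules), extracts
    12-month hospitalization, surgery and emergency-department outcomes with
    ED reclassification, computes annualized 2017-USD expenditures per cost
    category, and compares response-probability strata with Pearson
    chi-square tests, one-way ANOVA and two-sample t-tests (including
    summary-statistics variants). Ships a synthetic-claims generator with
    stratum-dependent event rates and right-skewed costs so the full
    pipeline is testable without proprietary data, and a verification
    routine that recomputes the published summary tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
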