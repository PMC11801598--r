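Package: t2dcea
Title: Markov Cohort Cost-Effectiveness Model for Type 2 Diabetes Therapies
Version: 0.1.0
Authors@R: person("Model", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Deterministic Markov cohort simulation of long-term diabetes
    complications for two-arm cost-effectiveness analysis from a health-system
    perspective. Parallel complication sub-models (eye, lower extremity, renal,
    macrovascular, heart failure) driven by UKPDS-style risk equations, a
    treatment-switch rule on HbA1c, event/state cost and QALY accrual with
    discounting, incremental cost-effectiveness with dominance classification,
    one-way deterministic sensitivity analysis and second-order Monte Carlo
    probabilistic sensitivity analysis with cost-effectiveness acceptability
    curves. Ships a fully documented reference parameterization (2022 CNY) for
    IDegLira versus GLP-1RA plus basal insulin in Chinese type 2 diabetes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
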