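Package: edumort
Title: Educational Inequalities in Premature Adult Mortality from
    Prospective Cohort Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies educational and social inequalities in premature
    adult mortality from prospective cohort data. Provides Lexis splitting
    of follow-up into 5-year age-at-risk bands, sex- and age-band-stratified
    Cox partial-likelihood estimation with delayed entry and cause-specific
    censoring, floated (group-specific) variances so every exposure category
    carries its own confidence interval, likelihood-ratio chi-square
    mediation attenuation, and calibration of study rate ratios to national
    death rates to project survival curves and partial life-expectancy gaps
    by education. A synthetic-cohort generator with education-graded
    mediator distributions and piecewise-constant cause-specific hazards
    makes every stage of the pipeline testable at desk scale.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
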