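Package: crosswise
Title: Estimation and Design Tools for the Extended Crosswise Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Prevalence estimation and survey design for the extended
    crosswise model (ECWM), a randomized response technique for sensitive
    questions. Provides moment and maximum likelihood estimators, binary
    logistic regression on randomized responses, the one degree of freedom
    likelihood-ratio goodness-of-fit test with boundary handling,
    comparison statistics against direct questioning, Monte Carlo
    validation (parameter recovery, test calibration, power), and
    generation of number-sequence randomizer items with exactly known
    randomization probabilities. Ships the observed response frequencies
    of three UK validation surveys on controlled substance use and
    COVID-19 lockdown compliance as a worked dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
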