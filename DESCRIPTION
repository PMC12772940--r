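Package: retrodict
Title: Bayesian Retrodiction of Medication Adherence from Therapeutic Drug
    Monitoring
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Clinical trial simulation toolkit for inferring recent
    medication-taking behavior from a single therapeutic drug monitoring
    concentration. Declarative population pharmacokinetic model
    specifications are simulated by Monte Carlo under all 2^n hypotheses
    about the last n scheduled doses (taken/missed bitstrings); Bayes'
    rule converts the conditional concentration distributions and scenario
    priors into posterior probability curves, discrimination thresholds,
    a complete/partial/none retrodiction classification and
    single-observation adherence assessments, with sensitivity sweeps over
    renal function, comedication, formulation interval, sampling time,
    priors and residual error.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
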