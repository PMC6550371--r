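Package: crmobayes
Title: Expert Prior Elicitation and Bayesian Design for a Two-Arm Trial
    in Chronic Nonbacterial Osteomyelitis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying expert prior opinion about a two-arm
    randomised trial of adalimumab versus pamidronate in chronic
    nonbacterial osteomyelitis (CNO/CRMO), where the endpoint is the
    26-week change in pain score on a 100 mm visual analogue scale.
    Implements a conjugate Normal-Gamma opinion model with Student-t
    parameter marginals and patient predictive distributions; fits
    predictive distributions to threshold-probability elicitation
    answers by a quantile-transform regression; aggregates an expert
    panel to a consensus answer set; calibrates hyperparameters from
    published prior summaries; performs exact conjugate updating with
    two-arm trial summary statistics; and estimates the operating
    characteristics of a posterior-probability decision rule for a
    clinically relevant treatment difference by Monte-Carlo simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
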