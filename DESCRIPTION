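Package: confsig
Title: Statistical Signatures of Bayesian Decision Confidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Monte Carlo simulation and analysis of objective decision
    confidence in two-alternative forced-choice tasks. Implements the
    standard Bayesian model of confidence (posterior probability of a
    correct choice given identity evidence and the choice) and a general
    model in which confidence is additionally informed by noisy trial-level
    evidence about stimulus discriminability. Provides discriminability
    priors with quadrature support, a seeded trial simulator, vectorized
    posterior scoring, conditional confidence curves with folded-X versus
    double-increase pattern classification, and the conditional entropy of
    accuracy given confidence.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    pracma,
    readr,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
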