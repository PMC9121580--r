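Package: ftndmiss
Title: Simulation Study of Methods for Managing Missing Items on the
    Fagerstrom Test for Nicotine Dependence
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to compare strategies for scoring the six-item
    Fagerstrom Test for Nicotine Dependence (FTND) when respondents skip
    individual items.  Provides a calibrated latent-trait generator for
    synthetic FTND populations, MAR and MNAR item-missingness mechanisms
    based on logistic subject-eligibility models, six scoring methods
    (complete case analysis, drop one, item mean with and without the
    half rule, proration, and k-nearest-neighbour Gower hot deck), and a
    Monte Carlo driver that measures bias and standard-error bias of the
    mean FTND score and of a regression coefficient across a grid of
    missingness conditions.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
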