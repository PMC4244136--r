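Package: rdsmix
Title: Contact-Network Analysis of Online Respondent-Driven Sampling Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing social contact networks collected with online
    respondent-driven sampling (webRDS) surveys of the kind used to study
    contact patterns relevant for the transmission of respiratory pathogens.
    Provides a validated recruitment-forest data model with delimited-text I/O,
    a synthetic survey generator with tunable homophily and Markov order,
    negative-binomial degree-distribution fitting with parametric-bootstrap
    confidence intervals, Anderson-Darling k-sample and Kolmogorov-Smirnov
    two-sample comparisons, assortative-mixing correlations by link distance in
    recruitment trees, a first-order-Markov check on recruitment chains,
    effective contact rates from contact-rate means and variances, and logistic
    models of the intention to recruit peers online.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    yaml
Suggests:
    MASS,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
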