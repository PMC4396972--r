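Package: tumorcontrol
Title: Tumor Control Probability for a Two-Compartment Active/Quiescent
    Stochastic Model of Radiotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the tumor control probability (TCP) for a stochastic
    two-compartment birth-death model of actively dividing and quiescent
    tumor cells under radiotherapy. Active cells divide asymmetrically
    (each daughter is active with probability f), quiescent cells
    re-activate at a constant rate, and both compartments carry distinct,
    possibly time-dependent, radiation-induced death rates derived from the
    linear-quadratic dose-response model. Provides the exact steady-state
    TCP and phase diagrams via fixed points of the probability generating
    function, a time-resolved TCP solver based on a final-value method of
    characteristics, an exact Gillespie stochastic-simulation estimator
    with binomial confidence bounds, and the one-compartment
    Zaider-Minerbo closed form as a reference limit.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
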