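Package: chronocycle
Title: Circadian-Gated Cell-Cycle Population Dynamics and Chronomodulated
    Treatment Scheduling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A linear delay-differential population model of proliferating
    tissue in which the circadian clock gates the G1-S transition rate and
    modulates the G2 phase duration.  The package simulates host and tumor
    cell populations under cell-cycle phase-specific cytotoxic treatment
    delivered as chronomodulated (truncated-Gaussian) or flat infusions,
    scores treatment schedules by a tolerance-versus-efficacy outcome
    evaluated seven days after the first administration, and implements an
    analytic predictor (period-averaged growth-rate perturbation integrals)
    of best and worst administration times, non-24 h schedule equivalences,
    and a clock-free resonance analysis via the Lambert W function.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
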