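Package: ph2design
Title: Optimal, Minimax and Admissible Two-Stage Designs for Single-Arm
    Phase II Trials
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Exact design and evaluation of single-arm two-stage phase II
    clinical trials with a binary (tumour response) endpoint.  Computes
    exact binomial operating characteristics (attained type I error,
    power, probability of early termination, expected sample size under
    the null) for Simon's futility-only stopping rule and for Fleming's
    rule with both futility and efficacy stopping; searches exhaustively
    for the minimax and optimal designs under (alpha, beta) constraints;
    and classifies the per-n expected-sample-size-minimising candidate
    designs into admissible and inadmissible designs by the Bayes risk of
    the loss q*n + (1-q)*EN, reporting the weight interval over which each
    admissible design is the Bayes design.  A Monte Carlo trial simulator
    and a command-line interface for reproducing design tables and
    EN-versus-n curve data are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
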