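Package: dmaxent
Title: Dynamic Maximum Entropy Reduction of Stochastic Population Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reduces one-dimensional stochastic dynamics governed by a
    Fokker-Planck equation to a low-dimensional deterministic system for
    "effective forces" via a dynamic maximum entropy (quasi-stationary
    exponential-family) ansatz. Ships two worked models -- the
    Ornstein-Uhlenbeck process, for which the reduction is exact, and a
    stochastic logistic island model with immigration, for which it is an
    accurate approximation valid for migration rate m > 1/2 -- together with
    the full validation stack: seeded Euler-Maruyama ensembles, a
    conservative Chang-Cooper Fokker-Planck solver with no-flux boundaries,
    a birth-death transition-matrix reference, confluent-hypergeometric
    moment calculus, and relative-entropy error tracking for abrupt and
    periodic environmental change.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
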