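Package: entropage
Title: Entropy-Based Models of Tissue Degradation and Biological Age
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying biological degradation and tissue age
    through entropy. Provides discrete entropy functionals (statistical
    entropy, Kullback-Leibler relative entropy over compartment density
    profiles, multinomial combinatorial entropy), a discrete-velocity
    BGK-type kinetic relaxation model with local equilibrium and
    nonequilibrium entropy profiles and an integrated entropy-difference
    age statistic, a seeded stochastic compartment simulator of epithelial
    aging (fast multiplicative metabolic noise plus slow thinning) with
    Kullback-Leibler trajectory tracking, and allometric timescale
    arithmetic linking heartbeat period, metabolic time and lifetime into
    the degradation invariant N = T/tau.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    pracma,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
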