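Package: anticonf
Title: Anticonformity and Preference Expression on Social Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agent-based simulation of binary choice under heterogeneous
    preferences and social (anti)conformity on Erdos-Renyi and
    Barabasi-Albert networks, using a logistic (Fermi) decision rule with
    asynchronous updates. Includes generators for networks with a target
    correlation between node degree and anticonformity, degree-preserving
    assortative rewiring, time-varying environments (linear and sinusoidal
    net-preference schedules), outcome metrics (choice-preference
    alignment, volatility, tipping and lead times, welfare), and a
    well-mixed mean-field companion with fixed-point, bifurcation and
    exact finite-population Markov-chain analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
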