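Package: oscomm
Title: Evolutionary Game Dynamics of Communication in Oscillator Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates the evolution of costly communication in networks of
    identical-period oscillators, an abstraction of the mammalian
    suprachiasmatic nucleus. Each oscillator carries a strategy pairing a
    communication flag with one of d discrete phases; payoffs come from a
    2d x 2d cost/benefit matrix over cyclic phase distance, and populations
    evolve by a death-birth process on all-to-all, von Neumann (4-neighbor),
    Moore (8-neighbor) and probabilistic spatial topologies. Includes game
    region classification (Prisoner's Dilemma, snowdrift, coordination,
    mutualism), exact absorbing Markov-chain fixation probabilities for small
    systems, parameter-sweep orchestration, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    Matrix,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
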