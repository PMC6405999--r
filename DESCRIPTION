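Package: tagdilemma
Title: Spatial Donation Game with Observable Binary Labels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulator and analysis toolkit for an evolutionary donation game
    on graphs in which every agent carries a static, observable binary label
    (green or blue) and strategies may condition cooperation on the partner's
    label. Agents update asynchronously by fitness-proportional imitation of
    a neighbour, with exponential payoff-to-fitness mapping and rare uniform
    mutation. The package builds lattice, line, ring and random-graph
    populations with gradient, uniform or patterned label fields; runs the
    all-defector phase-scan protocol over the cooperation benefit and the
    selection pressure; and implements the one-dimensional domain-boundary
    birth-death-chain theory (stationary ratios, closed-form discrimination
    condition, transition lines for repeated label patterns) together with a
    direct Monte-Carlo oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    grDevices,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
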