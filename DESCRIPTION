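Package: normdyn
Title: Two-Population Replicator Dynamics of Cooperation, Norms, and Conflict
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Game-dynamical replicator equations for two interacting
    populations with incompatible preferences and unequal power. Classifies
    symmetric 2x2 games (prisoner's dilemma, snowdrift, stag hunt, harmony)
    from the payoff-difference parameters B = S-P and C = R-T, integrates the
    coupled two-population replicator flow on the unit square, enumerates and
    classifies all stationary solutions (corners, edge points, interior points
    and equilibrium continua) via the affine structure of the growth brackets,
    maps basins of attraction, sweeps parameters for phase diagrams and
    discontinuous ("revolutionary") transitions, applies costly-punishment and
    group-pressure payoff transformations, and provides a finite-population
    proportional-imitation counterpart whose mean dynamics reproduce the
    replicator flow.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
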