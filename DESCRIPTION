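Package: hiercoop
Title: Hierarchy and Cooperation in a Two-Stage Threshold Game
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for a two-stage economic game in
    which pairs drawn from a ranked group first play a threshold cooperation
    game (joint contributions must reach 20 units to double the pot to 40) and
    then split the pot in an ultimatum game whose rejection outside option is a
    lottery with rank-dependent winning probability. Provides the game rules
    and payoff accounting for five treatments (no hierarchy, earned or random
    hierarchy, with and without the cooperation phase), an exact
    subgame-perfect equilibrium solver by backward induction together with a
    brute-force enumeration of the contribution-stage pure Nash equilibria,
    rational, inequity-averse (Fehr-Schmidt) and empirically calibrated agent
    policies, a seeded synthetic-study generator reproducing the full
    round-robin design, and the statistical pipeline: Helmert-style treatment
    contrasts, dyad-level bootstrap confidence intervals, four regression model
    families, and per-figure summary tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    optparse,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
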