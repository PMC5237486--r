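Package: donorgap
Title: Supply-Demand Gap Modelling for Altruistic Sperm Donation Programs
Version: 0.1.0
Authors@R:
    person("Donor Gap", "Modelling Group", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Deterministic, scenario-driven population models for the
    feasibility of an altruistic sperm donation program. Implements a
    top-down supply funnel (a population base filtered through awareness,
    willingness, presentation and medical-eligibility proportions, capped
    by an allowable-live-births policy), a three-segment demand model for
    donor insemination (same-sex female couples, single women, and
    heterosexual couples with male-factor infertility), supply-demand gap
    and break-even analysis, one-way parameter sweeps, a binomial-thinning
    Monte Carlo for uncertainty quantification, and a synthetic census-like
    population-table generator. Scenario parameters are stored losslessly
    (exact rationals or fixed-precision decimals) so published scenario
    tables reproduce cell-for-cell.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
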