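Package: dynafba
Title: Dynamic Genome-Scale Flux Balance Simulation of Batch Fermentations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates anaerobic batch fermentations of Saccharomyces
    cerevisiae with a dynamic flux balance model: a stoichiometric metabolic
    model is solved repeatedly by linear programming under experimentally
    motivated kinetic constraints (hexose transport with glucose/fructose
    competition and ethanol inhibition, saturable nitrogen uptake, condition
    dependent ATP maintenance, and a time- and medium-specific biomass
    equation), and the resulting exchange rates are integrated through the
    bioreactor mass balances over fixed intervals.  Supports anaerobic
    constraint sets (oxygen, TCA branching, quinone reactions, sterol
    uptake), in-silico genetic modifications (deletions, insertions,
    over/under-expression), bi-level (lexicographic) objectives with a
    parsimonious tie-break, and validation scoring against experimental
    fermentation profiles and mutant endpoint tables.  Ships a fully
    elementally balanced toy fermentation network and a synthetic-experiment
    generator so that every component is testable without external model
    files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    xml2,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
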