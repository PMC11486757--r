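Package: chemoflux
Title: Chemostat Mass-Balance Physiology and Measurement-Constrained
    Parsimonious Flux Balance Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of nutrient-excess response in chemostat
    cultivations: specific rate and Cmol yield calculations with carbon-balance
    closure from reactor mass balances, flux balance analysis and parsimonious
    FBA over stoichiometric models (SBML L3+fbc subset and a native JSON
    dialect), Monte-Carlo sampling of measured exchange-rate bounds with
    ensemble averaging, pathway-normalized flux reporting with flux-map overlay
    export, differential-expression thresholding with Benjamini-Hochberg FDR
    control, and a synthetic-data generator producing chemostat time series
    with known true rates, hand-solvable toy metabolic networks, and
    planted-truth gene tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tibble,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
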