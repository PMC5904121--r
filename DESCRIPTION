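Package: rumpdesign
Title: Flux Balance Design of Methanol-Essential Escherichia coli Strains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Constraint-based design of synthetic methylotrophy. Implements
    flux balance analysis (FBA) on stoichiometric metabolic models, growth
    coupled knockout screening that renders methanol an essential co-substrate
    via the ribulose monophosphate (RuMP) cycle, carbon-13 isotopologue
    labeled-fraction analysis with natural-abundance correction, and
    estimation of growth and specific substrate uptake rates from culture
    time series with evaporation control and error propagation. Ships a
    hand-built Escherichia coli core model reproducing the pathway topology
    relevant to gluconate/methanol co-assimilation, a bounded-variable
    simplex solver for the FBA linear programs, and seeded generators for
    synthetic growth, substrate and isotopologue data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    xml2,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
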