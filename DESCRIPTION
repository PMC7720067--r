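Package: smcplan
Title: Microplanning of Door-to-Door Seasonal Malaria Chemoprevention Campaigns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to plan door-to-door seasonal malaria chemoprevention (SMC)
    delivery by community health workers (CHWs) in rural villages. Extracts
    household locations and family sizes from gridded population rasters or
    point tables, computes shortest open visit itineraries (exact Held-Karp
    dynamic programming and a multi-start nearest-neighbour/2-opt heuristic),
    subdivides hard-to-reach villages with minimum-size constrained k-means
    (assignment step solved as a transportation problem), and simulates
    campaigns under a CHW time budget to quantify coverage and unmet workforce
    needs. Includes a synthetic village generator with uniform, random and
    clumped dispersion regimes and an end-to-end pipeline producing
    scenario-comparison reports and GeoJSON map layers.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    geosphere,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
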