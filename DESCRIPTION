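Package: sprawlsim
Title: Cellular-Automaton Simulation and Projection of Urban Sprawl
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for business-as-usual urban growth projection on raster
    landscapes. Delineates urban extent from street-network line density,
    calibrates a SLEUTH-style cellular automaton (spontaneous, spreading-
    center, edge and road-influenced growth with self-modification) against
    a multi-date urban series by exhaustive coarse-to-fine coefficient
    search, projects growth with Monte Carlo ensembles, and summarises
    land-cover conversion and landscape fragmentation with patch metrics.
    Includes a synthetic-landscape generator (terrain, hierarchical street
    networks, autocorrelated land cover) for end-to-end testing without
    external GIS data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
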