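Package: netspat
Title: Network-Constrained Point Pattern Analysis of Urban Facilities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing point events that live on a road network:
    weighted and unweighted network kernel density estimation with a
    Gaussian kernel evaluated in shortest-path distance, network auto and
    cross K-functions with Monte Carlo complete-spatial-randomness
    envelopes and cluster/random/dispersed classification, street
    centrality indices (betweenness, closeness, straightness) with planar
    kernel density surfaces, and raster-level Spearman correlation between
    facility density and street centrality. Includes a synthetic-city
    generator (grid networks, network-constrained CSR, clustered and
    regular point processes, facility attributes) so the full pipeline is
    testable without proprietary GIS layers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
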