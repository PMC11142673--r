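Package: climcorridor
Title: Mapping and Prioritizing Climate Adaptation Corridors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies and prioritizes potential climate adaptation corridors
    linking lowland protected areas to intact highland forest refugia. Cleans
    reserve polygon tables, selects lowland start nodes and upper-montane
    forest end patches, builds a structural conductance surface from land
    cover and forest biomass, traces least-cost paths on the raster lattice
    between each start node and its five nearest end points, summarizes
    corridor ecology and conservation status with buffered zonal and overlay
    statistics, and ranks corridors with a PCA-based priority index (distance
    from the origin in the space of the first three principal components)
    classified into low, medium, and high priority. Includes a seeded
    synthetic-landscape generator so the whole pipeline can be exercised and
    tested without external geodata, plus the nonparametric comparison
    battery (Spearman, Kruskal-Wallis, Dunn with Holm adjustment) used to
    contrast priority classes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    mgcv
Config/testthat/edition: 3
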