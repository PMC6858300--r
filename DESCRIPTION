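Package: trophoscape
Title: Trophic Guilds, Community Trophic Structures and Their Climatic and
    Human Drivers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to identify trophic guilds of large mammals from
    diet-composition matrices by fuzzy c-means clustering, to detect how many
    well-defined community trophic structures exist in a gridded species
    assemblage using an average-membership-degree (AMD) cluster validity
    statistic, to model the relationship between trophic structures and
    bioclimatic variables with evolutionary (globally optimised)
    classification trees, and to quantify human-impact-driven transitions
    between structures.  Includes a synthetic-data generator (Gaussian
    cluster benchmarks, archetype-based diet matrices, and a gridded world
    with climate, land use, population and islands) so the whole pipeline can
    be exercised without external data, plus bipartite resource-to-guild
    energy-flow networks and Cohen's kappa map agreement.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    randomForest,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    e1071,
    mclust,
    optparse,
    rpart,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
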