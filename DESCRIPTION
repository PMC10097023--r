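Package: longicore
Title: Mining Longevity-Associated Core Gut Microbiota from 16S OTU Tables
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Weighted co-abundance network analysis of 16S rRNA OTU tables
    for discovering core gut microbiota associated with a host trait such as
    longevity. Builds soft-thresholded adjacency and topological overlap
    matrices, detects co-abundance modules by dynamic cutting of an
    average-linkage dendrogram, correlates module eigengenes with sample
    traits, extracts hub taxa by maximal neighbourhood component (MNC)
    centrality, and intersects them with dual random-forest importance
    rankings to nominate core genera. Also provides alpha-diversity indices,
    phylum ratios and PERMANOVA, a PCA-based composite probiotic strain
    score gated by the Kaiser-Meyer-Olkin statistic, 2^-ddCt qPCR relative
    expression, and a synthetic-data generator emulating the statistical
    structure of amplicon cohorts so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite
Config/testthat/edition: 3
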