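Package: xylemnet
Title: Co-Expression Network Analysis of Wood-Development Cryosection Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing replicated tangential cryosection series of
    developing secondary xylem, from a raw gene-by-sample count matrix to a
    signed mutual-information/CLR co-expression network, developmental gene
    clusters, expression-domain assignments, gene-set enrichment and
    cross-species neighbourhood-conservation reports. Includes a negative
    binomial simulator of cryosection series and two-species regulatory
    modules so every stage can be exercised and validated without external
    data, a closed-form negative binomial variance-stabilising transform,
    scale-free threshold selection for the network, and network centrality
    summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    splines,
    stats,
    utils,
    yaml
Suggests:
    withr,
    mclust,
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
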