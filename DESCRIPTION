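Package: coexmod
Title: Differential Protein Abundance and Permutation-Thresholded
    Co-Expression Modules
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of multiplexed (TMT-style) proteomics
    experiments across oxygen-tension and drug-treatment conditions:
    abundance filtering and log2 transformation, empirical-Bayes moderated
    t-statistics for pairwise condition contrasts, classification of
    treatment-restored proteins, hypergeometric gene-set over-representation,
    co-expression network inference with per-edge permutation z-scores and a
    dual weight/z threshold, Girvan-Newman edge-betweenness community
    detection with a modularity cut, a module-level fold-change reversal
    test, and comparison against a curated knowledge-based interaction
    network. A synthetic-data generator with planted differential,
    restored and module structure makes every stage testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    mclust,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    igraph,
    yaml,
    optparse
Config/testthat/edition: 3
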