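Package: phytometrics
Title: Scientometrics of Medicinal-Plant Research Corpora
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for scientometric analysis of bibliographic corpora on
    medicinal plants and herbal medicines: reading and cleaning Scopus-style
    CSV exports (deduplication, entity-name normalization), bibliometric
    indicators (annual series, entity rankings, shares, citation ratios),
    co-authorship and keyword co-occurrence networks with modularity-based
    community detection, and a text classifier that assigns publications to
    grouped Technology Readiness Level (TRL) categories by comparing abstract
    representations against anchor-keyword sets under Jaccard, Hellinger,
    Kullback-Leibler, and Jensen-Shannon distances, optionally expanded with
    latent Dirichlet allocation topics.  A synthetic-corpus generator with
    known ground truth (collaboration blocks, TRL labels, injected duplicates)
    makes every pipeline stage testable without proprietary database exports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    igraph,
    jsonlite,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2,
    yaml
LinkingTo:
    Rcpp
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
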