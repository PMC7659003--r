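Package: perturbnet
Title: Network-Based Detection of Subtle Perturbations in Time-Series
    Microbiome Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to detect subtle community-level perturbations (such as
    bioaugmentation of an anaerobic digester) from paired time-series
    16S family-level abundance tables.  Implements abundance-feature
    classification (high/low/rare levels, core membership, paired
    differential tests), co-occurrence correlation clustering, ensemble
    generalized Lotka-Volterra interaction-network inference with
    sign-coherence reliability filtering, a centrality-based topological
    niche statistic compared across interaction-strength levels, and a
    directed 3-/4-node network-motif census with degree- and
    reciprocity-preserving null-model significance.  A fully seeded
    synthetic community generator with known interaction matrices and
    planted abundance structure supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    vegan,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
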