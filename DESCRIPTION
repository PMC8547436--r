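Package: chemcov
Title: Chemical Diversity Coverage Planning for Natural Product Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative tools for designing natural product screening
    libraries from LC-MS metabolomics of microbial isolate collections.
    Processes aligned feature tables (blank filtering, total-ion-current
    normalization, replicate merging, binarization), partitions isolates by
    chemistry (Bray-Curtis distances, principal-coordinate analysis,
    hierarchical clustering with silhouette-based selection of the number of
    clusters, PERMANOVA), measures chemical richness and its accumulation
    (exact sample-based rarefaction, collector's curves, incidence-based
    Chao2 extrapolation, coverage-target solving, saturation slopes),
    consolidates features into scaffolds by modified-cosine molecular
    networking, and reports core/unique metabolome partitions, ordered
    group-wise accumulation, and geographic ranges. Includes a seeded
    synthetic-data generator that emulates a clade-structured isolate
    collection with known ground truth for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cluster,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    vegan,
    withr,
    yaml
Config/testthat/edition: 3
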