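Package: ulsl
Title: Unified Latent and Similarity Learning for Multi-Omics Subtype Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Joint learning of a shared low-dimensional latent representation
    and a fused sample-similarity graph from two or more omics views measured
    on a common sample set. Per-view affinity matrices are fused by similarity
    network fusion into a reference graph; an alternating optimizer then
    refines per-view projection matrices (ADMM with unit-norm columns), the
    shared latent matrix (Sylvester equation) and a row-stochastic similarity
    graph (simplex projections). Subtype labels are obtained by spectral
    clustering of the learned graph, with eigengap and gap-statistic model
    selection. Includes a synthetic multi-omics generator in which each view
    separates only a subset of the subtypes, so that only integration recovers
    the full structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    cluster,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
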