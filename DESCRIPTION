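Package: canyuns
Title: Evidence-Weighted Procedural Reconstruction of Metabolic Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds organism-specific genome-scale metabolic network
    reconstructions by contextualizing a curated universal biochemical
    network with genomic alignment evidence and binary phenotypic growth
    data. Reaction bitscores are mapped to weights in [-1, 1] by a
    step-wise linear transform and drive data-guided flux balance analysis
    (dgFBA), a linear program that maximizes weighted flux while requiring
    biomass production. Flux-carrying reactions tracked per growth
    condition yield direction-specific certainty values that determine
    reaction inclusion. Includes free-mass curation of the universal
    network, parsimonious FBA comparison, rarefaction of flux-carrying
    reaction accumulation, conditional-essentiality pruning by net
    benefit, discovery-accuracy comparison against a reference
    reconstruction, and a synthetic scenario generator with planted ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
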