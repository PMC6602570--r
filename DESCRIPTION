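Package: respnet
Title: Minimum-Cost-Flow Inference of Signaling and Regulatory Subnetworks
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Infers sparse, high-probability subnetworks that connect a source
    set of proteins to a target set of genes, proteins or microRNAs by routing
    flow through a typed human interactome at minimum cost, the optimum of a
    linear program over edge flows. Includes a typed interactome data model
    with TSV/JSON input and output, construction of tissue-specific
    interactomes from raw RNA-seq counts (prefiltering, TMM normalization to
    counts per million, per-tissue median expression calls, PPI filtering),
    set algebra over predicted subnetworks, empirical node significance by
    degree-matched randomization, synthetic benchmark generators with planted
    ground truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    edgeR,
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
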