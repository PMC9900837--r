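Package: columncensus
Title: Columnar Connectomics of Inhibitory Circuitry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for synapse-resolution connectomics of a
    cortical column: compartment labeling of neuronal skeletons (soma
    collapse, synapse-flow-centrality axon split, false-merge pruning,
    apical-branch scoring), data-driven inhibitory subclass and excitatory
    morphological-type (M-type) classification via consensus Leiden
    clustering, inhibitory motif-group discovery from synaptic output
    budgets, and a shuffle-null Selectivity Index with Holm-Sidak
    correction. Includes a synthetic cortical column generator with
    planted ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    igraph,
    randomForest,
    cluster,
    jsonlite,
    mixOmics
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
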