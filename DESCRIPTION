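Package: connhub
Title: Hub Neuron Characterization and Community Detection in Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analyzing the input network of a hub neuron in a
    synaptic connectome. Reads neuprint-style neuron annotation and
    adjacency tables, ranks neurons by synaptic endowment, classifies
    cell types by primacy (whether the hub is their top aggregated
    output) and reciprocity, extracts the induced subconnectome of a
    hub's presynaptic partners, detects communities by maximizing
    generalized modularity density with a reduced-network extremal
    ensemble learning scheme, and validates modules via co-membership
    Jaccard comparison, joint-proportion matrices, permutation-null
    input-vector cosine similarity, and neuropil supercategory
    profiles. Includes a synthetic connectome generator with planted
    modular structure for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
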