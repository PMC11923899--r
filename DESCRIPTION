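Package: cortexclust
Title: Spatial Clustering of Excitatory and Inhibitory Neurons in Cortical Sections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects spatial clusters of excitatory and inhibitory neurons in
    2-D cortical sections by sliding-window permutation enrichment, merges
    overlapping significant windows into neuron clusters, and characterises
    them: excitation-inhibition ratios, nearest-neighbour distances,
    interregional span, excitatory-inhibitory cluster partnerships, cell
    subtype co-occurrence under a label-permutation null, and the relation of
    cluster composition to annotated functional systems and cortical
    hierarchy. Includes a layer-stratified synthetic scene generator with
    planted enriched clusters so every stage can be validated against known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    vegan,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
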