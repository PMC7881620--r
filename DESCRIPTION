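Package: rigidom
Title: Rigid-Domain Detection in Protein Conformational Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects rigid domains in proteins from two or more
    conformational states. Residues are represented as vertices of a
    contact graph whose edges are weighted by the variance of inter-residue
    distances across conformations. The graph is coarse-grained with the
    Louvain community-detection algorithm, transformed into a modified line
    graph, and a binary edge labeling is inferred by exact maximum a
    posteriori (MAP) inference in a pairwise conditional random field.
    Negatively labeled edges split the coarse graph into candidate domains,
    which are refined recursively and post-processed with a merging routine.
    The number of rigid domains is determined automatically. Includes
    segmentation-comparison metrics, a synthetic hinge-motion ensemble
    generator for validation, and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    igraph,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
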