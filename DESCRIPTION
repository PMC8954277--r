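Package: bios2net
Title: Sequence- and Structure-Based Protein Fold Classification with
    Point-Cloud Neural Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Featurizes protein structures as ordered 53-feature atom point
    clouds (coordinates, crystallographic descriptors, secondary structure,
    accessible surface area, amino-acid identity, physicochemical scales and
    PSSM evolutionary profiles) and classifies protein folds with a hybrid
    neural architecture: a 1D inception sequence extractor, a PointNet++-style
    hierarchical set-abstraction structure extractor, a structure-aware
    temporal network over sequence-ordered centroids, and a weighted-fusion
    classifier with auxiliary losses. Includes a synthetic fold-class
    generator so the full pipeline runs self-contained, plus tools for
    dataset splitting, training with Adam, accuracy evaluation and global
    feature-vector extraction for embedding analyses.
License: MIT
Encoding: UTF-8
Imports:
    bio3d,
    pracma,
    stats,
    utils,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
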