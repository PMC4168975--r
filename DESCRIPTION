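Package: pocketalign
Title: Sequence Order-Independent Alignment and Similarity Scoring of
    Protein Ligand-Binding Pockets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Aligns predicted ligand-binding pockets of unrelated proteins
    without assuming any conservation of sequence order. Seven residue-pair
    scores (sequence profile, secondary structure, hydrophobicity
    correlation, binding probability, neighbor-distance distribution,
    sequence entropy, and template-ligand geometry) feed a support vector
    regression model that estimates inter-residue distances; the
    Kuhn-Munkres assignment algorithm turns the predicted distance matrix
    into an optimal residue correspondence. Six pocket-level features
    (pocket RMSD, averaged model scores, virtual-screening rank
    correlation, physicochemical differences, and a sorted-distance-list
    geometric score) are combined by a calibrated classifier into a pocket
    similarity probability. A synthetic pocket-pair generator with planted
    correspondences makes the whole pipeline trainable and testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    e1071,
    igraph,
    bio3d,
    ChemmineR,
    pROC,
    Biostrings,
    jsonlite,
    optparse,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
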