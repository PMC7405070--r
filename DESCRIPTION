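Package: claustrotype
Title: Intrinsic Electrophysiology Feature Extraction and Cell-Type
    Classification for Claustrum Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying claustrum neurons from whole-cell
    current-clamp recordings of 1-s current steps. Extracts up to 63
    canonical intrinsic electrical properties (passive properties, action
    potential waveform, afterhyperpolarization and afterdepolarization
    descriptors, spike-train adaptation and Cv2 variability statistics),
    reproduces the unsupervised taxonomy (Z-scoring, Pearson/average-linkage
    and Euclidean/Ward hierarchical clustering with silhouette-based model
    selection, t-SNE and locally linear embeddings), applies Q10 temperature
    correction between recording temperatures, and runs a three-stage
    PCA-plus-neural-network classifier assigning one of eight cell types
    (five projection-neuron subtypes and PV, SST, and VIP interneurons).
    A synthetic-data module samples feature-table cohorts from the published
    subtype distributions and simulates subtype-typical spiking traces so the
    whole pipeline can be exercised without raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    nnet,
    purrr,
    readr,
    rlang,
    Rtsne,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    ape,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
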