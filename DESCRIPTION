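Package: hsomact
Title: Hierarchical Self-Organizing Maps for Online Skeleton Action Recognition
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A three-layer hierarchical self-organizing-map (SOM) architecture
    for recognizing actions in unsegmented streams of 3D skeleton postures.
    Includes the preprocessing chain (ego-centered coordinate transform,
    size scaling, velocity-based joint attention), a generic SOM lattice with
    Gaussian-neighborhood competitive learning, key-activation extraction and
    fixed-length pattern-window segmentation, a cosine-metric supervised
    output layer, a certainty-gated streaming recognizer, readers and writers
    for MSR-style skeleton text and a canonical JSON format, and a seeded
    synthetic skeleton-action generator for end-to-end benchmarking.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
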