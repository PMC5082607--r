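Package: netannotate
Title: Automatic Cluster Annotation and Summarization for Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Summarizes modular networks by clustering nodes (Markov
    clustering or a node attribute), building a per-cluster word cloud
    from textual node attributes with network-frequency normalization,
    deriving a short semantic label per cluster via size-based or
    adjacency-aware word selection, drawing shape and label annotations
    over the layout, and optionally collapsing clusters into single
    labeled group nodes connected by meta-edges. Includes GraphML and
    edge-list readers and writers, a JSON session format, an SVG
    renderer, a synthetic fixture generator with planted clusters and
    word themes, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr,
    xml2
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
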