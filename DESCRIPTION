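Package: ontropy
Title: Entropy-Aware Path-Based Quality Metrics for Biomedical Ontologies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies redundancy in OWL/OBO ontologies with an
    entropy-aware path-based (EAPB) metric. An ontology is parsed into a
    simple undirected class graph with per-class text; structure-based and
    text-based vertex embeddings are learned jointly (biased random walks
    with a skip-gram objective, plus a convolutional text encoder with
    mutual attention), an information-gain matrix is derived from cosine
    similarity normalised by shortest-path length, and a weighted
    connectivity entropy summarises how evenly information is spread over
    the class graph. Includes a seed-deterministic synthetic-ontology
    generator with controllable redundancy, summary statistics and
    granularity profiling, a text-ablation mode, and multi-ontology
    comparison scoring.
License: MIT
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
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
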