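Package: tenosig
Title: Comparative Signaling Network Analysis of Tendon Development
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds and compares species- and stage-specific signaling
    networks of tenogenesis from literature-curated molecular interaction
    collections. Provides schema-validated readers and writers for directed
    interaction tables, network construction with an undirected simple-graph
    view, a topological parameter suite with scale-free (power-law)
    assessment, hub identification by the mean-plus-k-standard-deviations
    degree rule, a from-scratch Markov Cluster Algorithm, hypergeometric
    over-representation analysis with Benjamini-Hochberg false discovery
    rate control, iterative network expansion from a scored interaction
    source, three-layer signaling stratification, Venn-style set
    comparisons, seeded synthetic-data generators emulating the curated
    collection's structure, and a reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
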