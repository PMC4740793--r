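Package: pcstnet
Title: Drug-Modulation Sub-Network Inference with Prize-Collecting Steiner Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers the sub-network of a protein-protein interaction (PPI)
    network through which a drug's binding targets modulate downstream gene
    expression. Each putative target is used as the root of a rooted
    Prize-Collecting Steiner Tree (PCST) over a confidence-weighted PPI
    (edge cost = 1 - confidence), collecting differentially expressed
    "leaf" genes within a bounded network depth. Sub-networks are scored by
    the participation of their intermediate (cryptic) nodes in curated key
    pathways, normalized against random-root control cohorts, compared
    between cohorts with Welch's t-test, and mined for critical nodes by
    betweenness centrality at the 95th percentile. Includes readers and
    writers for STRING-style edge lists, GMT gene sets and gene lists, a
    deterministic synthetic-data generator with planted target-to-leaf
    paths for end-to-end validation, over-representation analysis with
    Benjamini-Hochberg correction, and binding-assay (%Control) utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
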