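Package: enrichdag
Title: Weighted DAG-Aware Ontology Enrichment Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Over-representation analysis for gene sets annotated to a
    rooted ontology (Disease Ontology and other OBO-format DAGs) using a
    double-weighted hypergeometric model. Genes inherited along the
    true-path rule receive decaying initial weights, and a bottom-up
    traversal of the ontology levels dynamically down-weights genes of
    locally less significant terms, alleviating the parent-term
    over-enrichment caused by annotation inheritance. Includes an OBO
    parser, true-path annotation propagation, dictionary-based text
    annotation, seeded synthetic ontology and annotation generators, and
    simulation-based accuracy and perturbation-robustness studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
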