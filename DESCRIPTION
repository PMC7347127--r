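Package: ontosim
Title: Ontology Semantic Similarity, Enrichment Analysis and Functional
    Similarity Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ontology-agnostic toolkit for biomedical ontologies in OBO
    format. Parses OBO term graphs and tab-separated annotation corpora,
    computes corpus-based information content, and implements eleven
    between-term semantic similarity measures (Resnik, Lin, Jiang-Conrath,
    Schlicker relevance, their GraSM disjoint-common-ancestor variants,
    two edge-based measures and the Wang hybrid measure) together with
    eleven between-entity measures (four pairwise combiners and seven
    groupwise set measures). Also provides term-enrichment analysis with
    Fisher's exact and binomial tests under Bonferroni or
    Benjamini-Hochberg correction, functional-similarity network
    construction with min/max thresholds, edge-list weighting, set-vs-set
    similarity, deterministic synthetic ontology/corpus generators, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
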