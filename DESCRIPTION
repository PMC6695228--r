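Package: goscope
Title: Scoping-Aware Gene Ontology Traversal and Annotation Enrichment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Parses Gene Ontology OBO flat files into a relation-typed graph
    and applies scoping-semantics-aware traversal policies, including the
    reinterpretation of has_part edges as part_of_some so that every scoping
    edge points from the narrower to the broader term. Quantifies the
    hypothetical false term mappings produced by native has_part
    directionality and the mappings lost when has_part is omitted, emulates a
    non-discriminating slim mapper to measure its error fraction, reads GAF
    2.x gene-association files, propagates annotations through ancestor maps,
    performs one-sided hypergeometric annotation enrichment with
    Benjamini-Hochberg correction, and compares paired enrichment results
    between traversal policies with an exact one-sided binomial test.
    Includes seeded generators for synthetic ontologies, annotation files and
    differential-expression tables with ground-truth ledgers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
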