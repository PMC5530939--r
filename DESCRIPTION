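Package: diseasetree
Title: Inferring Disease Hierarchies from Disease-Gene Associations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers rooted hierarchies of disease terms from disease-gene
    association data via Parent Promotion (complete-linkage hierarchical
    clustering on Jaccard gene-set distances followed by citation-driven
    promotion of cluster representatives) and a rooted minimum-weight
    spanning tree baseline. Includes readers for OBO ('is_a') ontologies and
    MeSH-style tree-number tables, reference preprocessing that prunes terms
    lacking gene annotations while preserving ancestry, hierarchy comparison
    metrics (edge correctness, ancestor correctness, ancestor
    precision/recall and F), and a synthetic-data generator with separable
    fixtures guaranteeing exact recovery.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
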