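Package: ontorank
Title: Ontology-Enriched Vector-Space Ranking of Rule-Based Concept
    Definitions in Text
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies which rule-based concept definitions from a domain
    knowledge base (an ontology class hierarchy plus a Horn-like rule base)
    occur in short passages of scientific text. Snippets are modelled as
    tf-idf vectors; each candidate rule is modelled either by the raw terms
    of the concept it defines (term-based) or by a semantic vector that adds
    terms of hierarchy neighbours weighted by 2^(-shortest-path distance).
    Rules are ranked by cosine similarity. Includes canonical syntactic rule
    signatures for template matching of previously unseen concepts, a
    three-scenario rank-based evaluation protocol with an exact Wilcoxon
    signed-rank comparison, and a seeded synthetic generator of knowledge
    bases and annotated snippet corpora for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
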