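test_that("the packaged hierarchy fixture loads with its concepts and rules", {
  kb <- fig1_kb()
  expect_s3_class(kb, "knowledge_base")
  expect_gte(length(kb$concepts), 6L)
  expect_length(kb$rules, 2L)
  expect_identical(kb$rules_by_concept$delayed_words, "delayed_words_rule")
  expect_identical(nrow(kb$unresolved), 0L)
})

test_that("an empty document yields an empty knowledge base without error", {
  f <- withr::local_tempfile(fileext = ".json")
  writeLines('{"concepts": [], "properties": [], "rules": []}', f)
  kb <- load_kb(f)
  expect_length(kb$concepts, 0L)
  expect_length(kb$rules, 0L)
})

test_that("a rule referencing a missing concept is recorded, not dropped", {
  f <- withr::local_tempfile(fileext = ".json")
  writeLines('{
    "concepts": [{"id": "a", "label": "Alpha", "parents": []}],
    "rules": [{"id": "r1", "defines": "ghost",
               "body": [], "head": [{"pred": "ghost", "kind": "class", "args": ["?x"]}]}]
  }', f)
  kb <- load_kb(f)
  expect_length(kb$rules, 1L)
  expect_identical(nrow(kb$unresolved), 1L)
  expect_identical(kb$unresolved$ref, "ghost")
})

test_that("malformed input and cyclic hierarchies raise informative errors", {
  f <- withr::local_tempfile(fileext = ".json")
  writeLines('{"concepts": [', f)
  expect_error(load_kb(f), "parse error")
  expect_error(
    knowledge_base(concepts = list(
      list(id = "a", label = "A", parents = "b"),
      list(id = "b", label = "B", parents = "a"))),
    "cyclic")
  expect_error(
    knowledge_base(concepts = list(list(id = "a", label = "   "))),
    "empty label")
})

test_that("hierarchy distances follow undirected shortest paths", {
  kb <- fig1_kb()
  expect_identical(shortest_path_distance(kb, "delayed_words", "status_age_words"), 1)
  expect_identical(shortest_path_distance(kb, "delayed_words", "delayed_words"), 0)
  expect_identical(shortest_path_distance(kb, "delayed_words", "language_acquisition"), 2)
  # siblings are reachable through the shared parent
  expect_identical(shortest_path_distance(kb, "delayed_words", "no_words"), 2)
  # the instrument concept has no links into the hierarchy
  expect_identical(shortest_path_distance(kb, "delayed_words", "adi_r"), Inf)
  expect_error(shortest_path_distance(kb, "delayed_words", "nope"), "unknown concept")
})

test_that("distance is symmetric, triangular, and matches breadth-first search", {
  withr::local_seed(7)
  for (rep in 1:10) {
    kb <- random_kb(n_concepts = sample(5:30, 1))
    ids <- names(kb$concepts)
    trip <- sample(ids, 3, replace = TRUE)
    dab <- shortest_path_distance(kb, trip[1], trip[2])
    expect_identical(dab, shortest_path_distance(kb, trip[2], trip[1]))
    dac <- shortest_path_distance(kb, trip[1], trip[3])
    dbc <- shortest_path_distance(kb, trip[2], trip[3])
    expect_lte(dac, dab + dbc)
    expect_equal(dab, bfs_distance(kb, trip[1], trip[2]))
  }
})

test_that("semantic similarity halves per hop and is 0 when disconnected", {
  kb <- fig1_kb()
  expect_identical(semantic_similarity(kb, "delayed_words", "status_age_words"), 0.5)
  expect_identical(semantic_similarity(kb, "delayed_words", "delayed_words"), 1.0)
  expect_identical(semantic_similarity(kb, "delayed_words", "autism_phenotype_level"),
                   0.125)
  expect_identical(semantic_similarity(kb, "delayed_words", "adi_r"), 0)
  # strictly decreasing, halving per unit step, down the ancestor chain
  chain <- c("delayed_words", "status_age_words", "language_acquisition",
             "autism_phenotype_level")
  sims <- unname(vapply(chain, function(c2)
    semantic_similarity(kb, "delayed_words", c2), numeric(1)))
  expect_true(all(diff(sims) < 0))
  expect_equal(sims[-1], sims[-length(sims)] / 2)
})

test_that("the JSON dialect round-trips a knowledge base identically", {
  kb <- fig1_kb()
  f <- withr::local_tempfile(fileext = ".json")
  write_kb(kb, f)
  kb2 <- load_kb(f)
  expect_identical(kb$concepts, kb2$concepts)
  expect_identical(kb$properties, kb2$properties)
  expect_identical(kb$rules, kb2$rules)
  expect_identical(kb$rules_by_concept, kb2$rules_by_concept)
})

test_that("turtle and RDF/XML imports recover the class hierarchy", {
  ttl <- withr::local_tempfile(fileext = ".ttl")
  writeLines(c(
    '@prefix ex: <http://example.org/onto#> .',
    '@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .',
    'ex:delayed_words rdfs:label "Delayed Words" ; rdfs:subClassOf ex:status_age_words .',
    'ex:status_age_words rdfs:label "Status of Age of Words" .'), ttl)
  kb <- load_kb(ttl)
  expect_setequal(names(kb$concepts), c("delayed_words", "status_age_words"))
  expect_identical(kb$concepts$delayed_words$parents, "status_age_words")
  expect_identical(kb$concepts$delayed_words$label, "Delayed Words")

  rdf <- withr::local_tempfile(fileext = ".rdf")
  writeLines(c(
    '<rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"',
    '         xmlns:rdfs="http://www.w3.org/2000/01/rdf-schema#"',
    '         xmlns:owl="http://www.w3.org/2002/07/owl#">',
    '  <owl:Class rdf:about="http://example.org/onto#delayed_words">',
    '    <rdfs:label>Delayed Words</rdfs:label>',
    '    <rdfs:subClassOf rdf:resource="http://example.org/onto#status_age_words"/>',
    '  </owl:Class>',
    '  <owl:Class rdf:about="http://example.org/onto#status_age_words">',
    '    <rdfs:label>Status of Age of Words</rdfs:label>',
    '  </owl:Class>',
    '</rdf:RDF>'), rdf)
  kb2 <- load_kb(rdf)
  expect_identical(kb2$concepts$delayed_words$parents, "status_age_words")
  expect_identical(shortest_path_distance(kb2, "delayed_words", "status_age_words"), 1)
})

test_that("removal helpers are pure and keep indexes consistent", {
  kb <- fig1_kb()
  snapshot <- fig1_kb()
  kb2 <- remove_rule(kb, "delayed_words_rule")
  expect_length(kb2$rules, 1L)
  expect_false("delayed_words" %in% names(kb2$rules_by_concept))
  kb3 <- remove_concept(kb, "delayed_words")
  expect_false("delayed_words" %in% names(kb3$concepts))
  expect_length(kb3$rules, 1L)
  expect_identical(kb$rules, snapshot$rules)
  expect_identical(kb$concepts, snapshot$concepts)
})
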