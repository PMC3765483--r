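test_that("the signed-rank test is exact for small samples", {
  res <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5))
  expect_identical(res$statistic, 15)
  expect_equal(res$p_value, 2 / 2^5)
  expect_identical(res$method, "exact")

  sym <- wilcoxon_signed_rank(c(1, -1))
  expect_equal(sym$p_value, 1)

  expect_error(wilcoxon_signed_rank(c(0, 0)), "zero")
})

test_that("exact p-values equal full sign-flip enumeration, ties included", {
  withr::local_seed(3)
  for (rep in 1:50) {
    n <- sample(3:10, 1)
    d <- sample(c(-4:-1, 1:4), n, replace = TRUE)  # many tied |differences|
    got <- wilcoxon_signed_rank(d)
    expect_identical(got$method, "exact")
    expect_equal(got$p_value, enumerate_wilcoxon_p(d), tolerance = 1e-12)
  }
})

test_that("tie-free exact p-values agree with the reference implementation", {
  withr::local_seed(13)
  for (rep in 1:20) {
    n <- sample(4:12, 1)
    d <- sample(seq(1, 40), n) * sample(c(-1, 1), n, replace = TRUE)
    got <- wilcoxon_signed_rank(d)
    ref <- stats::wilcox.test(d, exact = TRUE)
    expect_equal(got$statistic, unname(ref$statistic))
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("large samples fall back to a tie-corrected normal approximation", {
  withr::local_seed(19)
  d <- sample(c(-5:-1, 1:5), 40, replace = TRUE)
  got <- wilcoxon_signed_rank(d)
  expect_identical(got$method, "normal_approximation")
  ref <- stats::wilcox.test(d, exact = FALSE, correct = TRUE)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
})

scenario_fixture <- function() {
  kb <- knowledge_base(
    concepts = list(
      list(id = "P", label = "category words"),
      list(id = "A", label = "alpha", parents = "P"),
      list(id = "B", label = "beta")),
    rules = list(simple_rule("rA", "A"), simple_rule("rB", "B")))
  corpus <- build_corpus(list(
    list(id = "s1", text = "alpha words words category category beta beta"),
    list(id = "s2", text = "padding text only")))
  gold <- gold_annotations("s1", "A", list("rA"))
  list(kb = kb, corpus = corpus, gold = gold)
}

test_that("a trivially matching snippet gives rank 1 under both methods", {
  kb <- knowledge_base(
    concepts = list(list(id = "c", label = "delayed words")),
    rules = list(simple_rule("r", "c")))
  corpus <- build_corpus(list(
    list(id = "s1", text = "delayed words delayed words criteria"),
    list(id = "s2", text = "unrelated other content")))
  gold <- gold_annotations("s1", "c", list("r"))
  rep1 <- evaluate_scenario1(kb, corpus, gold)
  expect_equal(unname(rep1$average_rank["semantic"]), 1)
  expect_equal(unname(rep1$average_rank["term_based"]), 1)
  expect_identical(names(rep1$per_item_ranks$semantic),
                   names(rep1$per_item_ranks$term_based))
})

test_that("a parent-label term in the snippet lifts the semantic rank above term-based", {
  fx <- scenario_fixture()
  rep1 <- evaluate_scenario1(fx$kb, fx$corpus, fx$gold)
  expect_lt(rep1$per_item_ranks$semantic[["s1|A"]],
            rep1$per_item_ranks$term_based[["s1|A"]])
})

test_that("gold annotations must resolve before any ranking happens", {
  fx <- scenario_fixture()
  bad <- gold_annotations("s1", "A", list("no_such_rule"))
  expect_error(evaluate_scenario1(fx$kb, fx$corpus, bad), "unknown ids")
  expect_error(gold_annotations(c("s1", "s1"), c("A", "A"), list("r", "r")),
               "duplicate")
})

test_that("scenario 2 scores surviving alternatives after each removal", {
  kb <- knowledge_base(
    concepts = list(list(id = "c", label = "delayed words"),
                    list(id = "d", label = "other thing")),
    rules = list(simple_rule("r1", "c", cutoff = "24"),
                 simple_rule("r2", "c", cutoff = "30"),
                 simple_rule("rd", "d")))
  corpus <- build_corpus(list(
    list(id = "s1", text = "delayed words appear here"),
    list(id = "s2", text = "unrelated filler material")))
  gold <- gold_annotations("s1", "c", list(c("r1", "r2")))
  rep2 <- evaluate_scenario2(kb, corpus, gold)
  expect_identical(rep2$scenario, "alternative")
  expect_identical(sort(names(rep2$per_item_ranks$semantic)),
                   c("s1|c|r1", "s1|c|r2"))
  # alternative rules share the removed rule's vector, hence its rank
  full <- rank_rules("s1", corpus,
                     vectorize_rulebase(kb, vectorizer_config("term_based")), "t")
  expect_equal(unname(rep2$per_item_ranks$term_based[["s1|c|r1"]]),
               rank_of("r1", full))

  only_single <- knowledge_base(
    concepts = list(list(id = "c", label = "delayed words")),
    rules = list(simple_rule("r1", "c")))
  expect_error(evaluate_scenario2(only_single, corpus,
                                  gold_annotations("s1", "c", list("r1"))),
               "at least 2 rule definitions")
})

test_that("scenario 2's subset shortcut matches a naive rebuild per removal", {
  b <- generate_benchmark(synth_params(n_concepts = 21, branching = 4,
                                       tree_depth = 2, defined_fraction = 0.8,
                                       snippets = 6, seed = 3))
  rep_fast <- evaluate_scenario2(b$kb, b$corpus, b$gold)
  cfgs <- list(semantic = vectorizer_config("semantic"),
               term_based = vectorizer_config("term_based"))
  multi <- names(b$kb$rules_by_concept)[
    vapply(b$kb$rules_by_concept, length, integer(1)) >= 2L]
  items <- b$gold[b$gold$concept_id %in% multi, , drop = FALSE]
  for (m in names(cfgs)) {
    naive <- numeric(0)
    for (i in seq_len(nrow(items))) {
      cid <- items$concept_id[[i]]; sid <- items$snippet_id[[i]]
      for (removed in b$kb$rules_by_concept[[cid]]) {
        kb2 <- remove_rule(b$kb, removed)
        res <- rank_rules(sid, b$corpus, vectorize_rulebase(kb2, cfgs[[m]]), m)
        naive[[paste(sid, cid, removed, sep = "|")]] <-
          rank_of(setdiff(b$kb$rules_by_concept[[cid]], removed), res)
      }
    }
    expect_identical(rep_fast$per_item_ranks[[m]][names(naive)], naive)
  }
})

test_that("scenario 3 ranks the deleted concept's template among survivors", {
  kb <- fig1_kb()
  corpus <- fig1_corpus()
  gold <- gold_annotations(c("snippet2", "snippet2"),
                           c("delayed_words", "delayed_phrases"),
                           list("delayed_words_rule", "delayed_phrases_rule"))
  rep3 <- evaluate_scenario3(kb, corpus, gold)
  # with one structurally identical rule surviving, it is the bearer
  expect_equal(unname(rep3$per_item_ranks$semantic[["snippet2|delayed_words"]]), 1)
  expect_equal(unname(rep3$per_item_ranks$term_based[["snippet2|delayed_words"]]), 1)
  expect_identical(rep3$n_excluded, 0L)
  expect_identical(names(rep3$per_item_ranks$semantic),
                   names(rep3$per_item_ranks$term_based))
})

test_that("scenario 3 items with no surviving template are excluded and counted", {
  kb <- knowledge_base(
    concepts = list(list(id = "a", label = "alpha thing"),
                    list(id = "b", label = "beta item"),
                    list(id = "c", label = "gamma part")),
    rules = list(
      simple_rule("ra", "a"),
      kb_rule("rb", "b",   # structurally unique: no surviving bearer
              body = list(rule_atom("p1", "data_property", c("?x", "?v")),
                          rule_atom("q_rel", "object_property", c("?x", "?y"))),
              head = list(rule_atom("b", "class", "?x"))),
      simple_rule("rc", "c")))
  corpus <- build_corpus(list(list(id = "s1", text = "alpha thing beta item"),
                              list(id = "s2", text = "noise words here")))
  gold <- gold_annotations(c("s1", "s1"), c("a", "b"), list("ra", "rb"))
  rep3 <- evaluate_scenario3(kb, corpus, gold)
  expect_identical(rep3$n_excluded, 1L)
  expect_identical(names(rep3$per_item_ranks$semantic), "s1|a")
})

test_that("evaluation leaves the knowledge base byte-identical", {
  b <- generate_benchmark(synth_params(n_concepts = 21, branching = 4,
                                       tree_depth = 2, defined_fraction = 0.8,
                                       snippets = 5, seed = 9))
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_kb(b$kb, f1)
  evaluate_scenario1(b$kb, b$corpus, b$gold)
  evaluate_scenario2(b$kb, b$corpus, b$gold)
  evaluate_scenario3(b$kb, b$corpus, b$gold)
  write_kb(b$kb, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("average ranks are at least 1 and recomputable from the items", {
  b <- generate_benchmark(synth_params(n_concepts = 21, branching = 4,
                                       tree_depth = 2, defined_fraction = 0.8,
                                       snippets = 5, seed = 9))
  rep1 <- evaluate_scenario1(b$kb, b$corpus, b$gold)
  for (m in c("semantic", "term_based")) {
    expect_gte(min(rep1$per_item_ranks[[m]]), 1)
    expect_equal(unname(rep1$average_rank[m]),
                 mean(rep1$per_item_ranks[[m]]))
  }
})
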