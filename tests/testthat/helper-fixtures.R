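# shared fixtures and independent oracles

fig1_kb <- function() {
  load_kb(system.file("extdata", "language_kb.json", package = "ontorank"))
}

fig1_corpus <- function() {
  read_snippets(system.file("extdata", "language_snippets.jsonl",
                            package = "ontorank"))
}

# minimal two-concept hierarchy: one child under one parent
child_parent_kb <- function(child_label = "Delayed Words",
                            parent_label = "Status of Age of Words") {
  knowledge_base(
    concepts = list(
      list(id = "parent", label = parent_label, parents = character(0)),
      list(id = "child", label = child_label, parents = "parent")))
}

simple_rule <- function(id, concept, prop = "p1", cutoff = "24") {
  kb_rule(id, concept,
          body = list(rule_atom(prop, "data_property", c("?a", "?v")),
                      rule_atom("swrlb:greaterThan", "builtin",
                                c("?v", cutoff))),
          head = list(rule_atom(concept, "class", "?a")))
}

# breadth-first search over undirected parent links, independent of igraph
bfs_distance <- function(kb, from, to) {
  if (from == to) return(0)
  adj <- lapply(kb$concepts, function(co) co$parents)
  for (co in kb$concepts)
    for (p in co$parents)
      adj[[p]] <- c(adj[[p]], co$id)
  dist <- stats::setNames(rep(Inf, length(kb$concepts)), names(kb$concepts))
  dist[[from]] <- 0
  frontier <- from
  while (length(frontier)) {
    nxt <- character(0)
    for (v in frontier) {
      for (w in adj[[v]]) {
        if (is.infinite(dist[[w]])) {
          dist[[w]] <- dist[[v]] + 1
          nxt <- c(nxt, w)
        }
      }
    }
    frontier <- nxt
  }
  dist[[to]]
}

# plain elementwise cosine over the union vocabulary
naive_cosine <- function(a, b) {
  vocab <- union(names(a), names(b))
  if (!length(vocab)) return(0)
  av <- stats::setNames(rep(0, length(vocab)), vocab)
  bv <- av
  av[names(a)] <- as.numeric(a)
  bv[names(b)] <- as.numeric(b)
  na <- sqrt(sum(av^2)); nb <- sqrt(sum(bv^2))
  if (na == 0 || nb == 0) return(0)
  sum(av * bv) / (na * nb)
}

# two-sided signed-rank p by full 2^n sign-flip enumeration
enumerate_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  v_all <- apply(signs, 1, function(s) sum(r[s]))
  p_le <- mean(v_all <= v_obs + 1e-9)
  p_ge <- mean(v_all >= v_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# random sparse nonnegative term vector over a small shared vocabulary
random_term_vector <- function(vocab, max_terms = 6L) {
  k <- sample.int(max_terms, 1L)
  terms <- sample(vocab, k)
  term_vector(stats::setNames(stats::runif(k, 0.1, 3), terms))
}

# random small KB whose every concept has a rule (for vector/ranking tests)
random_kb <- function(n_concepts = 8L, vocab_size = 20L) {
  vocab <- paste0("w", seq_len(vocab_size))
  concepts <- list(list(id = "n1", label = paste(sample(vocab, 2), collapse = " "),
                        parents = character(0)))
  for (i in 2:n_concepts) {
    concepts[[i]] <- list(
      id = paste0("n", i),
      label = paste(sample(vocab, sample(1:3, 1)), collapse = " "),
      parents = paste0("n", sample.int(i - 1L, 1L)))
  }
  rules <- lapply(seq_len(n_concepts), function(i) {
    r <- simple_rule(sprintf("r%02d", i), paste0("n", i))
    if (i %% 2 == 0)  # alternate shape: add an object-property assertion
      r$head <- c(r$head, list(rule_atom("q_rel", "object_property",
                                         c("?a", "?v"))))
    r
  })
  knowledge_base(concepts = concepts, rules = rules)
}
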