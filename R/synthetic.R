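#' Parameters for the synthetic benchmark generator
#'
#' The generator emulates the statistical structure of a curated phenotype
#' knowledge base and its annotated snippet corpus: a rooted class
#' hierarchy whose child labels share vocabulary with their parents, leaf
#' concepts defined by 1-3 threshold-style rules drawn from a handful of
#' syntactic shapes, and multi-definition snippets whose length follows a
#' truncated normal with mean 98 and standard deviation 42 terms, padded
#' with filler and sibling-concept distractor mentions.
#'
#' @param n_concepts number of hierarchy concepts (instruments excluded).
#' @param tree_depth maximum depth below the root.
#' @param branching children per internal node.
#' @param term_pool_size size of the pseudo-word vocabulary labels draw on.
#' @param rules_per_concept integer range `c(min, max)` of alternative rules
#'   per defined (leaf) concept.
#' @param defined_fraction fraction of leaf concepts that receive rules;
#'   the rest stay undefined, as in curated knowledge bases where the rule
#'   base covers a minority of the ontology's classes (and as the
#'   distractor mechanism requires).
#' @param snippets number of snippets to generate.
#' @param defs_per_snippet integer range of concept definitions verbalized
#'   per snippet.
#' @param snippet_len_mean,snippet_len_sd target snippet length (in raw
#'   whitespace terms), normal with floor 10.
#' @param distractor_rate probability, per verbalized definition, of also
#'   mentioning an undefined sibling concept.
#' @param label_share_prob probability that a child label carries one term
#'   of its parent's label (1 = always; 0 = disjoint vocabularies).
#' @param seed integer seed; the output is a pure function of the
#'   parameters including the seed.
#' @return a list of class `synth_params`.
#' @export
synth_params <- function(n_concepts = 85L, tree_depth = 3L, branching = 4L,
                         term_pool_size = 150L,
                         rules_per_concept = c(1L, 3L),
                         defined_fraction = 0.35,
                         snippets = 18L, defs_per_snippet = c(1L, 6L),
                         snippet_len_mean = 98, snippet_len_sd = 42,
                         distractor_rate = 0.2, label_share_prob = 1,
                         seed = 42L) {
  p <- list(n_concepts = as.integer(n_concepts),
            tree_depth = as.integer(tree_depth),
            branching = as.integer(branching),
            term_pool_size = as.integer(term_pool_size),
            rules_per_concept = as.integer(rules_per_concept),
            defined_fraction = as.numeric(defined_fraction),
            snippets = as.integer(snippets),
            defs_per_snippet = as.integer(defs_per_snippet),
            snippet_len_mean = as.numeric(snippet_len_mean),
            snippet_len_sd = as.numeric(snippet_len_sd),
            distractor_rate = as.numeric(distractor_rate),
            label_share_prob = as.numeric(label_share_prob),
            seed = as.integer(seed))
  counts <- c("n_concepts", "tree_depth", "branching", "term_pool_size",
              "snippets")
  for (k in counts)
    if (p[[k]] < 1L) stop(k, " must be positive", call. = FALSE)
  for (k in c("rules_per_concept", "defs_per_snippet")) {
    if (length(p[[k]]) != 2L || p[[k]][1] < 1L || p[[k]][2] < p[[k]][1])
      stop(k, " must be an increasing positive range c(min, max)",
           call. = FALSE)
  }
  for (k in c("distractor_rate", "label_share_prob"))
    if (p[[k]] < 0 || p[[k]] > 1)
      stop(k, " must lie in [0, 1]", call. = FALSE)
  if (p$defined_fraction <= 0 || p$defined_fraction > 1)
    stop("defined_fraction must lie in (0, 1]", call. = FALSE)
  capacity <- sum(p$branching^(0:p$tree_depth))
  if (capacity < p$n_concepts)
    stop("inconsistent params: a depth-", p$tree_depth, " tree with branching ",
         p$branching, " holds at most ", capacity, " concepts, fewer than ",
         p$n_concepts, call. = FALSE)
  structure(p, class = "synth_params")
}

# run code under a seed without disturbing the caller's RNG stream
with_rng <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", sample.kind = "Rejection")
  force(code)
}

term_pool <- function(size) {
  syll <- c("bal", "cor", "dex", "fen", "gam", "hol", "jur", "kel", "lum",
            "mon", "nar", "oss", "pex", "quil", "ros", "sil", "tav", "urn",
            "vol", "wex", "yar", "zem", "bri", "cla", "dro")
  words <- as.vector(t(outer(syll, syll, paste0)))
  words[seq_len(size)]
}

sample_range <- function(rng) if (rng[1] == rng[2]) rng[1] else
  sample(seq.int(rng[1], rng[2]), 1L)

#' Generate a synthetic knowledge base
#'
#' Builds a rooted hierarchy of `n_concepts` with multi-word labels from
#' the term pool; each child label shares a term with its parent with
#' probability `label_share_prob` (the hook the semantic method exploits).
#' Leaf concepts receive 1-3 threshold-style rules of a few fixed shapes
#' (instrument class atom + measurement data-property atom + builtin
#' comparison, asserting the concept in the head), so the rule base carries
#' at most a handful of distinct syntactic signatures. Also emits two
#' instrument concepts (outside the hierarchy) and the measurement
#' properties the rules use. Deterministic for a fixed seed.
#'
#' @param params a [synth_params()].
#' @return a [knowledge_base()].
#' @export
generate_kb <- function(params = synth_params()) {
  stopifnot(inherits(params, "synth_params"))
  with_rng(params$seed, generate_kb_impl(params))
}

generate_kb_impl <- function(params) {
  pool <- term_pool(params$term_pool_size)
  # a very small modifier vocabulary reused across branches, the way
  # clinical phenotype names reuse a handful of qualifiers
  # (delayed / not delayed / absent / reduced / atypical), and a modest
  # measure vocabulary reused across categories, the way ontology labels
  # reuse domain words (age / status / words / score); reuse of the
  # measure vocabulary is what makes distinct branches collide on label
  # terms, so that hierarchy context is needed to tell them apart
  modifiers <- pool[seq_len(min(5L, length(pool)))]
  measures <- pool[min(6L, length(pool)):min(15L, length(pool))]
  fresh_i <- 15L
  fresh <- function(k) {
    idx <- ((fresh_i + seq_len(k) - 1L) %% length(pool)) + 1L
    fresh_i <<- fresh_i + k
    pool[idx]
  }

  concepts <- list()
  add_concept <- function(id, label, parents = character(0)) {
    concepts[[id]] <<- list(id = id, label = label, parents = parents)
  }
  cid <- function(i) sprintf("c%03d", i)

  # internal category nodes get fresh two-term labels; leaf phenotypes are
  # <modifier> + a term shared with the immediate parent (the local
  # label-sharing of real class hierarchies), so vocabulary does not
  # percolate across branches
  add_concept(cid(1), paste(fresh(2), collapse = " "))
  queue <- list(list(id = cid(1), depth = 0L))
  total <- 1L
  while (length(queue) && total < params$n_concepts) {
    node <- queue[[1]]; queue <- queue[-1]
    if (node$depth >= params$tree_depth) next
    # siblings take distinct modifiers, so labels stay unique within a group
    node_mods <- sample(modifiers)
    for (b in seq_len(params$branching)) {
      if (total >= params$n_concepts) break
      total <- total + 1L
      at_leaf_depth <- node$depth + 1L == params$tree_depth
      at_parent_depth <- node$depth + 1L == params$tree_depth - 1L
      label <- if (at_leaf_depth) {
        parent_label <- strsplit(concepts[[node$id]]$label, " ")[[1]]
        second <- if (stats::runif(1) < params$label_share_prob)
          parent_label[length(parent_label)] else fresh(1L)
        paste(c(node_mods[((b - 1L) %% length(node_mods)) + 1L], second),
              collapse = " ")
      } else if (at_parent_depth) {
        # leaf-parent categories end in a shared measure word
        paste(c(fresh(1), sample(measures, 1L)), collapse = " ")
      } else {
        paste(fresh(2), collapse = " ")
      }
      add_concept(cid(total), label, node$id)
      queue[[length(queue) + 1L]] <- list(id = cid(total), depth = node$depth + 1L)
    }
  }

  hier_ids <- names(concepts)
  children <- unlist(lapply(concepts, `[[`, "parents"))
  leaves <- setdiff(hier_ids, children)

  # instruments live outside the hierarchy, like a diagnostic test catalogue
  instruments <- c("inst_a", "inst_b")
  add_concept("inst_a", paste(fresh(2), collapse = " "))
  add_concept("inst_b", paste(fresh(2), collapse = " "))

  properties <- list(
    list(id = "p_subject_key", label = paste(fresh(2), collapse = " "),
         kind = "data_property"),
    list(id = "p_has_quality", label = paste(fresh(2), collapse = " "),
         kind = "object_property"))
  # only a subset of leaves carries rules, mirroring knowledge bases whose
  # rule base covers a minority of ontology classes; experts encode whole
  # sibling groups at a time, so defined leaves cluster by parent, and the
  # remaining leaves are fair game as undefined distractor mentions
  n_def <- max(2L, ceiling(params$defined_fraction * length(leaves)))
  parent_of <- vapply(concepts[leaves], function(co)
    if (length(co$parents)) co$parents[[1]] else NA_character_, character(1))
  groups <- split(leaves, parent_of)
  groups <- groups[sample(length(groups))]
  defined_leaves <- character(0)
  for (g in groups) {
    if (length(defined_leaves) >= n_def) break
    # a random subset of each sibling group is encoded, so defined groups
    # come in mixed sizes (singletons included)
    take <- sample(seq_along(g), 1L)
    defined_leaves <- c(defined_leaves, sample(g, take))
  }
  defined_leaves <- sort(defined_leaves)

  # each category group is encoded with one syntactic shape: rules for
  # sibling phenotypes come from the same editing session and so share a
  # template, which is what makes template matching informative
  shape_of_parent <- new.env(parent = emptyenv())

  rules <- list()
  for (leaf in defined_leaves) {
    pid <- paste0("p_", leaf)
    # the measurement's name echoes a term of the phenotype's label, the
    # way instrument item names echo the phenotype branch they measure
    lab <- strsplit(concepts[[leaf]]$label, " ")[[1]]
    echo <- lab[length(lab)]
    properties[[length(properties) + 1L]] <-
      list(id = pid, label = paste(c(fresh(1), echo), collapse = " "),
           kind = "data_property")
    n_rules <- sample_range(params$rules_per_concept)
    inst <- sample(instruments, 1L)
    par <- if (length(concepts[[leaf]]$parents))
      concepts[[leaf]]$parents[[1]] else "<root>"
    if (is.null(shape_of_parent[[par]]))
      shape_of_parent[[par]] <- sample(1:5, 1L)
    for (k in seq_len(n_rules)) {
      rid <- sprintf("r_%s_%d", leaf, k)
      cutoff <- as.character(sample(3:48, 1L))
      cmp <- sample(c("swrlb:greaterThan", "swrlb:lessThanOrEqual"), 1L)
      rules[[length(rules) + 1L]] <-
        synth_rule(rid, leaf, inst, pid, cmp, cutoff, shape_of_parent[[par]])
    }
  }
  knowledge_base(concepts = unname(concepts), properties = properties,
                 rules = rules)
}

synth_rule <- function(rid, concept, inst, pid, cmp, cutoff, shape) {
  base <- list(rule_atom(inst, "class", "?a"),
               rule_atom(pid, "data_property", c("?a", "?v")),
               rule_atom(cmp, "builtin", c("?v", cutoff)))
  # a range criterion adds a second comparison on the measured value,
  # the way instrument cut-offs are sometimes given as intervals
  range_atom <- rule_atom("swrlb:lessThanOrEqual", "builtin",
                          c("?v", as.character(as.integer(cutoff) + 12L)))
  finding <- list(rule_atom("p_subject_key", "data_property",
                            c("?a", "?id")),
                  rule_atom("swrlx:createOWLThing", "builtin",
                            c("?q", "?id")))
  finding_head <- list(rule_atom(concept, "class", "?q"),
                       rule_atom("p_has_quality", "object_property",
                                 c("?id", "?q")))
  switch(shape,
    # (B)(CCD): classify the assessed subject directly
    kb_rule(rid, concept, base, list(rule_atom(concept, "class", "?a"))),
    # (B)(CCDD): adds the subject-key data property
    kb_rule(rid, concept,
            c(base, finding[1]),
            list(rule_atom(concept, "class", "?a"))),
    # (B)(BC)(CDD)(O): mint a finding individual and attach it
    kb_rule(rid, concept, c(base, finding), finding_head),
    # (BB)(CCD): interval criterion on the measured value
    kb_rule(rid, concept, c(base, list(range_atom)),
            list(rule_atom(concept, "class", "?a"))),
    # (BB)(BC)(CDD)(O): finding individual with an interval criterion
    kb_rule(rid, concept, c(base, list(range_atom), finding), finding_head))
}

#' Generate an annotated snippet corpus for a synthetic knowledge base
#'
#' Each snippet verbalizes several concept definitions in templated English
#' ("<concept label>, a form of <parent label>, is defined on the
#' <instrument> by <measurement> greater than <cut-off> months ..."),
#' optionally name-drops sibling concepts as distractors, and is padded
#' with filler vocabulary to a truncated-normal target length. Gold
#' annotations link each snippet to its verbalized concepts, with all of a
#' concept's alternative rules as correct answers. Deterministic for a
#' fixed seed (the corpus stream is offset from the knowledge-base stream
#' so the two draws do not collide).
#'
#' @param kb a [generate_kb()] result (any knowledge base with rules works).
#' @param params a [synth_params()].
#' @return a list with elements `corpus` (a [snippet_corpus][build_corpus()])
#'   and `gold` ([gold_annotations()]).
#' @export
generate_corpus <- function(kb, params = synth_params()) {
  stopifnot(inherits(params, "synth_params"))
  if (!length(kb$rules))
    stop("knowledge base has no rules to verbalize", call. = FALSE)
  with_rng(params$seed + 1L, generate_corpus_impl(kb, params))
}

generate_corpus_impl <- function(kb, params) {
  defined <- names(kb$rules_by_concept)
  filler <- paste0("filler", sprintf("%02d", 1:60))
  lab <- function(id) strsplit(kb$concepts[[id]]$label, " ")[[1]]
  prop_lab <- function(id) strsplit(kb$properties[[id]]$label, " ")[[1]]
  undefined_siblings_of <- function(cid) {
    parents <- kb$concepts[[cid]]$parents
    if (!length(parents)) return(character(0))
    sibs <- names(Filter(function(co) length(intersect(co$parents, parents)) > 0,
                         kb$concepts))
    setdiff(sibs, c(cid, defined))
  }
  parent_of <- vapply(kb$concepts[defined], function(co)
    if (length(co$parents)) co$parents[[1]] else NA_character_, character(1))

  rule_bits <- function(co) {
    rule <- kb$rules[[sample_one(kb$rules_by_concept[[co]])]]
    dp <- Filter(function(a) a$kind == "data_property" &&
                   a$pred != "p_subject_key", rule$body)[[1]]
    b <- Filter(function(a) a$kind == "builtin" &&
                  a$pred != "swrlx:createOWLThing", rule$body)[[1]]
    inst <- Filter(function(a) a$kind == "class", rule$body)[[1]]
    list(prop = dp$pred, inst = inst$pred,
         cmp = if (b$pred == "swrlb:greaterThan") c("greater", "than")
               else c("at", "most"),
         cutoff = b$args[[2]])
  }
  ancestors <- function(co) {
    parents <- kb$concepts[[co]]$parents
    if (!length(parents)) return(character(0))
    ctx <- lab(parents[1])
    gp <- kb$concepts[[parents[1]]]$parents
    if (length(gp)) ctx <- c(ctx, "under", lab(gp[1]))
    ctx
  }
  maybe_distractor <- function(co) {
    if (stats::runif(1) >= params$distractor_rate) return(character(0))
    sibs <- undefined_siblings_of(co)
    if (!length(sibs)) return(character(0))
    c("unlike", lab(sample_one(sibs)))
  }

  snippets <- list()
  g_sid <- character(0); g_cid <- character(0); g_rids <- list()
  for (i in seq_len(params$snippets)) {
    sid <- sprintf("syn%03d", i)
    target <- trunc_normal_len(params$snippet_len_mean, params$snippet_len_sd)
    # longer text sections define more phenotypes: cap the definition count
    # by the drawn length (~18 raw terms per definition) so the realized
    # lengths keep the target distribution
    k <- min(sample_range(params$defs_per_snippet), length(defined),
             max(1L, target %/% 18L))
    words <- character(0)
    chosen <- character(0)
    while (length(chosen) < k) {
      # most definitions enter by whole defined-sibling units, as in the
      # source articles that defined a category's phenotype groups
      # together; a definition is scattered (single, in passing) when no
      # whole multi-member unit fits the remaining budget, and sometimes
      # by choice
      open <- setdiff(defined, chosen)
      unit_sizes <- vapply(open, function(z)
        sum(parent_of[open] == parent_of[[z]], na.rm = TRUE), numeric(1))
      fits <- open[unit_sizes > 1L & unit_sizes <= k - length(chosen)]
      grouped <- length(fits) > 0L && stats::runif(1) < 0.65
      co <- sample_one(if (grouped) fits else open)
      group <- open[!is.na(parent_of[open]) &
                      parent_of[open] == parent_of[[co]]]
      if (grouped) {
        # group style: one category header, then each sibling phenotype
        # with its own measurement criterion, as in instrument-based
        # grouping tables; category vocabulary recurs around the header
        # the way articles restate the construct being stratified
        bits1 <- rule_bits(group[[1]])
        par1 <- kb$concepts[[group[[1]]]]$parents[1]
        words <- c(words, "stratified", "by", lab(par1),
                   "groups", "of", ancestors(group[[1]]),
                   "are", "defined", "on", lab(bits1$inst), "as", "follows")
        for (co2 in group) {
          bits <- rule_bits(co2)
          words <- c(words, lab(co2), "when", prop_lab(bits$prop),
                     bits$cmp, bits$cutoff, "months", maybe_distractor(co2))
          chosen <- c(chosen, co2)
          g_sid <- c(g_sid, sid); g_cid <- c(g_cid, co2)
          g_rids[[length(g_rids) + 1L]] <- kb$rules_by_concept[[co2]]
        }
      } else {
        # scattered style: a single definition phrased through its
        # category, naming the phenotype and its measurement in passing
        # and restating the surrounding construct
        bits <- rule_bits(co)
        par <- kb$concepts[[co]]$parents
        recap <- if (length(par)) c("variation", "in", lab(par[1]))
                 else character(0)
        words <- c(words, lab(co), "a", "form", "of", ancestors(co),
                   "is", "defined", "on", lab(bits$inst), "by",
                   prop_lab(bits$prop), bits$cmp, bits$cutoff, "months",
                   recap, maybe_distractor(co))
        chosen <- c(chosen, co)
        g_sid <- c(g_sid, sid); g_cid <- c(g_cid, co)
        g_rids[[length(g_rids) + 1L]] <- kb$rules_by_concept[[co]]
      }
    }
    if (length(words) < target)
      words <- c(words, sample(filler, target - length(words), replace = TRUE))
    snippets[[length(snippets) + 1L]] <-
      list(id = sid, text = paste(words, collapse = " "))
  }
  list(corpus = build_corpus(snippets),
       gold = gold_annotations(g_sid, g_cid, g_rids))
}

sample_one <- function(x) if (length(x) == 1L) x else sample(x, 1L)

trunc_normal_len <- function(mean, sd, floor = 10) {
  repeat {
    x <- round(stats::rnorm(1, mean, sd))
    if (x >= floor) return(x)
  }
}

#' Generate the full synthetic benchmark
#'
#' Convenience wrapper: knowledge base, corpus and gold annotations in one
#' call.
#'
#' @param params a [synth_params()].
#' @return a list with `kb`, `corpus`, `gold`.
#' @export
generate_benchmark <- function(params = synth_params()) {
  kb <- generate_kb(params)
  cg <- generate_corpus(kb, params)
  list(kb = kb, corpus = cg$corpus, gold = cg$gold)
}
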