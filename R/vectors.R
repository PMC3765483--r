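#' Vectorizer configuration for concept/rule vectors
#'
#' Two competing representations of a defined concept are supported. The
#' *term-based* method uses only the raw label terms. The *semantic* method
#' walks the class hierarchy and folds in the label terms of every concept
#' within `max_distance` hops, each weighted by the hop-halving similarity
#' `2^(-distance)`, summing contributions that land on the same term.
#'
#' @param method `"term_based"` or `"semantic"`.
#' @param max_distance hop cut-off for related concepts (semantic only).
#'   At the default 2, neighbour weights are 0.5 and 0.25; deeper neighbours
#'   contribute less than 0.25 and are usually noise.
#' @param term_source `"head_label"` (the defined concept's label only — the
#'   default) or `"all_labels"` (labels of every class and property predicate
#'   occurring in the rule; builtins never contribute).
#' @param include_property_hierarchy expand property labels through the
#'   property hierarchy as well (semantic + `all_labels` only; default off).
#' @param tokenizer a [tokenizer_config()] used on labels.
#' @return a list of class `vectorizer_config`.
#' @export
vectorizer_config <- function(method = c("term_based", "semantic"),
                              max_distance = 2L,
                              term_source = c("head_label", "all_labels"),
                              include_property_hierarchy = FALSE,
                              tokenizer = tokenizer_config()) {
  method <- match.arg(method)
  term_source <- match.arg(term_source)
  max_distance <- as.integer(max_distance)
  stopifnot(max_distance >= 0L)
  structure(list(method = method, max_distance = max_distance,
                 term_source = term_source,
                 include_property_hierarchy = isTRUE(include_property_hierarchy),
                 tokenizer = tokenizer),
            class = "vectorizer_config")
}

label_terms <- function(kb, id, config) {
  lab <- if (id %in% names(kb$concepts)) kb$concepts[[id]]$label
         else if (id %in% names(kb$properties)) kb$properties[[id]]$label
         else NULL
  if (is.null(lab)) return(character(0))
  tokenize(lab, config$tokenizer)
}

# label terms of the non-builtin predicates of a rule, one entry per
# occurrence; namespace prefixes are not terms (the tokenizer splits them
# off, but predicate labels — not ids — are the term source anyway).
rule_predicate_terms <- function(rule, kb, config, skip_head_concept = FALSE) {
  out <- character(0)
  for (a in c(rule$body, rule$head)) {
    if (a$kind == "builtin") next
    if (skip_head_concept && a$kind == "class" && a$pred == rule$defines) next
    out <- c(out, label_terms(kb, a$pred, config))
  }
  out
}

#' Term-based vector of a rule
#'
#' With `term_source = "head_label"` the vector holds the occurrence count
#' of each tokenized term of the defined concept's label (so "Delayed Words"
#' becomes `{delayed: 1, words: 1}`). With `"all_labels"` the label terms of
#' every class and property predicate in the rule contribute their counts.
#' No hierarchy expansion and no similarity weighting are applied.
#'
#' @param rule a [kb_rule()] (or its id in `kb`).
#' @param kb a [knowledge_base()].
#' @param config a [vectorizer_config()].
#' @return a [term_vector()].
#' @export
term_based_vector <- function(rule, kb, config = vectorizer_config("term_based")) {
  rule <- resolve_rule(kb, rule)
  if (!rule$defines %in% names(kb$concepts))
    stop("rule '", rule$id, "': head concept '", rule$defines,
         "' not in knowledge base", call. = FALSE)
  terms <- if (config$term_source == "head_label")
    label_terms(kb, rule$defines, config)
  else
    rule_predicate_terms(rule, kb, config)
  if (!length(terms)) return(term_vector())
  term_vector(stats::setNames(rep(1, length(terms)), terms))
}

resolve_rule <- function(kb, rule) {
  if (inherits(rule, "kb_rule")) return(rule)
  if (!rule %in% names(kb$rules))
    stop("unknown rule id: '", rule, "'", call. = FALSE)
  kb$rules[[rule]]
}

#' Semantic vector of a concept
#'
#' Every concept `c` within `max_distance` hops of the target (undirected
#' subclass links) contributes each tokenized term of its label at weight
#' `2^(-distance)` per occurrence; the target's own label enters at weight 1
#' and contributions landing on the same term are summed. With the hierarchy
#' of the packaged language-acquisition fixture, "words" in the vector of
#' *Delayed Words* gets 1 from its own label plus 0.5 from the immediate
#' parent *Status of Age of Words*.
#'
#' @param concept_id a concept id in `kb`.
#' @param kb a [knowledge_base()].
#' @param config a [vectorizer_config()] with `method = "semantic"`.
#' @return a [term_vector()].
#' @export
semantic_vector <- function(concept_id, kb,
                            config = vectorizer_config("semantic")) {
  check_concept(kb, concept_id)
  stopifnot(config$method == "semantic")
  d <- igraph::distances(kb$graph, v = concept_id)[1, ]
  within <- names(d)[is.finite(d) & d <= config$max_distance]
  terms <- character(0)
  weights <- numeric(0)
  for (cid in within) {
    tt <- label_terms(kb, cid, config)
    if (!length(tt)) next
    terms <- c(terms, tt)
    weights <- c(weights, rep(2^(-d[[cid]]), length(tt)))
  }
  if (!length(terms)) return(term_vector())
  term_vector(stats::setNames(weights, terms))
}

semantic_property_terms <- function(rule, kb, config) {
  # expansion of the rule's property predicates through the property
  # hierarchy, mirroring the class-side hop-halving weights
  terms <- character(0)
  weights <- numeric(0)
  pids <- unique(vapply(Filter(function(a)
    a$kind %in% c("object_property", "data_property"), c(rule$body, rule$head)),
    `[[`, character(1), "pred"))
  pids <- intersect(pids, names(kb$properties))
  for (pid in pids) {
    d <- igraph::distances(kb$property_graph, v = pid)[1, ]
    within <- names(d)[is.finite(d) & d <= config$max_distance & d > 0]
    for (q in within) {
      tt <- label_terms(kb, q, config)
      terms <- c(terms, tt)
      weights <- c(weights, rep(2^(-d[[q]]), length(tt)))
    }
  }
  stats::setNames(weights, terms)
}

#' Vectorize an entire rule base
#'
#' One vector per rule, in the knowledge base's rule order. For the
#' semantic method a rule's vector is the [semantic_vector()] of its head
#' concept; in `all_labels` mode the rule's body/head predicate label terms
#' are added at weight 1 per occurrence (the hierarchy expansion applies to
#' the defined concept only).
#'
#' @param kb a [knowledge_base()].
#' @param config a [vectorizer_config()].
#' @return a named list of [term_vector()]s keyed by rule id.
#' @export
vectorize_rulebase <- function(kb, config = vectorizer_config("semantic")) {
  out <- lapply(kb$rules, function(rule) {
    if (config$method == "term_based") {
      term_based_vector(rule, kb, config)
    } else {
      v <- semantic_vector(rule$defines, kb, config)
      if (config$term_source == "all_labels") {
        # head-concept class atoms are skipped: that label already entered
        # at weight 1 via the hierarchy expansion
        extra <- rule_predicate_terms(rule, kb, config, skip_head_concept = TRUE)
        if (length(extra))
          v <- term_vector(c(stats::setNames(as.numeric(v), names(v)),
                             stats::setNames(rep(1, length(extra)), extra)))
        if (config$include_property_hierarchy) {
          ph <- semantic_property_terms(rule, kb, config)
          if (length(ph))
            v <- term_vector(c(stats::setNames(as.numeric(v), names(v)), ph))
        }
      }
      v
    }
  })
  names(out) <- names(kb$rules)
  out
}

#' Dump rule vectors as TSV
#'
#' Columns `rule_id`, `term`, `weight`; rows ordered by rule id then term.
#'
#' @param vectors a named list of [term_vector()]s.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vectors <- function(vectors, path) {
  rows <- do.call(rbind, c(list(
    data.frame(rule_id = character(0), term = character(0),
               weight = numeric(0))),
    lapply(names(vectors), function(id) {
      v <- vectors[[id]]
      if (!length(v)) return(NULL)
      data.frame(rule_id = id, term = names(v), weight = as.numeric(v))
    })))
  rows <- rows[order(rows$rule_id, rows$term, method = "radix"), , drop = FALSE]
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
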