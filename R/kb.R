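#' @title Knowledge base: ontology class hierarchy plus Horn-like rule base
#'
#' @description
#' A `knowledge_base` holds the domain knowledge the ranking methods draw on:
#' a class hierarchy of named concepts (a DAG of subclass links), an optional
#' property catalogue, and a rule base of concept definitions. Rules are data
#' to be ranked against text; they are never executed.
#'
#' @name knowledge_base
NULL

ATOM_KINDS <- c("class", "object_property", "data_property", "builtin")

#' Construct a rule atom
#'
#' An atom is one predicate application inside a rule: a class membership
#' test, an object- or data-property assertion, or a builtin (e.g. a numeric
#' comparison). Arguments are variables (strings starting with `?`) or
#' constants (any other string; numeric cut-offs are stored as strings).
#'
#' @param pred predicate identifier (namespace prefixes are kept).
#' @param kind one of `"class"`, `"object_property"`, `"data_property"`,
#'   `"builtin"`.
#' @param args character vector of arguments, in order.
#' @return a list of class `rule_atom`.
#' @export
rule_atom <- function(pred, kind, args) {
  kind <- match.arg(kind, ATOM_KINDS)
  args <- as.character(args)
  if (kind == "class" && length(args) != 1L)
    stop("class atom '", pred, "' must have exactly 1 argument", call. = FALSE)
  if (kind != "class" && length(args) < 2L)
    stop(kind, " atom '", pred, "' must have at least 2 arguments", call. = FALSE)
  structure(list(pred = as.character(pred), kind = kind, args = args),
            class = "rule_atom")
}

is_variable <- function(arg) startsWith(arg, "?")

#' Construct a rule
#'
#' @param id rule identifier.
#' @param defines identifier of the concept this rule defines.
#' @param body,head lists of [rule_atom()]s. The head must contain a class
#'   atom whose predicate is `defines`.
#' @return a list of class `kb_rule`.
#' @export
kb_rule <- function(id, defines, body, head) {
  stopifnot(is.list(body), is.list(head))
  head_classes <- vapply(head, function(a) a$kind == "class" && a$pred == defines,
                         logical(1))
  if (!any(head_classes))
    stop("rule '", id, "': head must contain a class atom for '", defines, "'",
         call. = FALSE)
  structure(list(id = as.character(id), defines = as.character(defines),
                 body = body, head = head),
            class = "kb_rule")
}

#' Assemble a knowledge base from concepts, properties and rules
#'
#' Validates the type invariants: non-empty trimmed labels, acyclic
#' hierarchy, well-formed atoms. References from rules to concepts or
#' properties that do not resolve are *collected* in `$unresolved`, not
#' dropped: a partially specified knowledge base still loads, and the caller
#' decides whether unresolved references are fatal.
#'
#' @param concepts list of lists with fields `id`, `label`, `parents`
#'   (character vector, possibly empty).
#' @param properties list of lists with fields `id`, `label`, `kind`
#'   (`object_property`/`data_property`/`builtin`) and optionally `parents`.
#' @param rules list of [kb_rule()]s (or plain lists with the same fields).
#' @return an object of class `knowledge_base` with elements `concepts`,
#'   `properties`, `rules` (all named lists keyed by id), `rules_by_concept`
#'   (concept id -> character vector of rule ids), `unresolved` (data frame),
#'   and a cached undirected hierarchy `graph`.
#' @export
knowledge_base <- function(concepts = list(), properties = list(), rules = list()) {
  concepts <- lapply(concepts, normalize_concept)
  properties <- lapply(properties, normalize_property)
  rules <- lapply(rules, normalize_rule)

  cids <- vapply(concepts, `[[`, character(1), "id")
  pids <- vapply(properties, `[[`, character(1), "id")
  rids <- vapply(rules, `[[`, character(1), "id")
  for (nm in list(c("concept", cids), c("property", pids), c("rule", rids))) {
    dup <- unique(nm[-1][duplicated(nm[-1])])
    if (length(dup))
      stop("duplicate ", nm[1], " id(s): ", paste(dup, collapse = ", "),
           call. = FALSE)
  }
  names(concepts) <- cids
  names(properties) <- pids
  names(rules) <- rids

  # parent links must resolve and form a DAG
  for (co in concepts) {
    miss <- setdiff(co$parents, cids)
    if (length(miss))
      stop("concept '", co$id, "' has unknown parent(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
  }
  cyc <- hierarchy_cycle(concepts)
  if (!is.null(cyc))
    stop("class hierarchy is cyclic: ", paste(cyc, collapse = " -> "),
         call. = FALSE)

  unresolved <- collect_unresolved(rules, cids, pids)

  rules_by_concept <- split(
    vapply(rules, `[[`, character(1), "id"),
    factor(vapply(rules, `[[`, character(1), "defines"),
           levels = unique(vapply(rules, `[[`, character(1), "defines")))
  )

  kb <- structure(
    list(concepts = concepts, properties = properties, rules = rules,
         rules_by_concept = lapply(rules_by_concept, unname),
         unresolved = unresolved),
    class = "knowledge_base")
  kb$graph <- hierarchy_graph(kb)
  kb$property_graph <- property_graph(kb)
  kb
}

normalize_concept <- function(co) {
  label <- trimws(as.character(co$label %||% ""))
  if (!nzchar(label))
    stop("concept '", co$id %||% "<missing id>", "' has an empty label",
         call. = FALSE)
  list(id = as.character(co$id), label = label,
       parents = as.character(co$parents %||% character(0)))
}

normalize_property <- function(pr) {
  kind <- match.arg(pr$kind, c("object_property", "data_property", "builtin"))
  list(id = as.character(pr$id), label = trimws(as.character(pr$label %||% pr$id)),
       kind = kind, parents = as.character(pr$parents %||% character(0)))
}

normalize_rule <- function(r) {
  if (inherits(r, "kb_rule")) return(r)
  mk <- function(a) if (inherits(a, "rule_atom")) a else
    rule_atom(a$pred, a$kind, unlist(a$args))
  kb_rule(r$id, r$defines, lapply(r$body, mk), lapply(r$head, mk))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

collect_unresolved <- function(rules, cids, pids) {
  known <- c(cids, pids)
  rows <- list()
  for (r in rules) {
    if (!(r$defines %in% cids))
      rows[[length(rows) + 1L]] <-
        data.frame(rule_id = r$id, ref = r$defines, role = "head_concept")
    for (a in c(r$body, r$head)) {
      target <- if (a$kind == "class") cids else pids
      # builtins (swrlb:*, swrlx:*) need not be declared
      if (a$kind != "builtin" && !(a$pred %in% target) && a$pred != r$defines)
        rows[[length(rows) + 1L]] <-
          data.frame(rule_id = r$id, ref = a$pred, role = a$kind)
    }
  }
  if (!length(rows))
    return(data.frame(rule_id = character(0), ref = character(0),
                      role = character(0)))
  unique(do.call(rbind, rows))
}

# Kahn peeling: returns NULL for a DAG, otherwise the ids of one cycle.
hierarchy_cycle <- function(concepts) {
  edges <- lapply(concepts, `[[`, "parents")
  names(edges) <- vapply(concepts, `[[`, character(1), "id")
  repeat {
    sinks <- names(edges)[vapply(edges, length, integer(1)) == 0L]
    if (!length(sinks)) break
    edges <- edges[setdiff(names(edges), sinks)]
    edges <- lapply(edges, setdiff, sinks)
  }
  if (!length(edges)) return(NULL)
  # every remaining node has a parent among the remainder: walk until revisit
  trail <- character(0)
  node <- names(edges)[1]
  while (!node %in% trail) {
    trail <- c(trail, node)
    node <- intersect(edges[[node]], names(edges))[1]
  }
  c(trail[seq(match(node, trail), length(trail))], node)
}

hierarchy_graph <- function(kb) {
  ids <- names(kb$concepts)
  el <- do.call(rbind, lapply(kb$concepts, function(co) {
    if (!length(co$parents)) return(NULL)
    cbind(co$id, co$parents)
  }))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(ids), name = ids)
  if (!is.null(el)) g <- igraph::add_edges(g, t(el))
  g
}

property_graph <- function(kb) {
  ids <- names(kb$properties)
  el <- do.call(rbind, lapply(kb$properties, function(pr) {
    if (!length(pr$parents)) return(NULL)
    keep <- intersect(pr$parents, ids)
    if (!length(keep)) return(NULL)
    cbind(pr$id, keep)
  }))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(ids), name = ids)
  if (!is.null(el)) g <- igraph::add_edges(g, t(el))
  g
}

#' @export
print.knowledge_base <- function(x, ...) {
  cat("<knowledge_base>", length(x$concepts), "concepts,",
      length(x$properties), "properties,", length(x$rules), "rules\n")
  if (nrow(x$unresolved))
    cat("  unresolved references:", nrow(x$unresolved), "\n")
  invisible(x)
}

#' Load a knowledge base from disk
#'
#' The native format is a JSON dialect with top-level keys `concepts`
#' (`id`, `label`, `parents`), `properties` (`id`, `label`, `kind`,
#' optional `parents`) and `rules` (`id`, `defines`, `body`, `head`; atoms
#' as objects `{"pred", "kind", "args"}`, variables written `"?x"`).
#' Turtle and RDF/XML serializations can seed the *class hierarchy only*
#' (subclass axioms and label annotations); rules always enter through the
#' JSON dialect.
#'
#' @param path file path.
#' @param format `"json"`, `"turtle"` or `"rdfxml"`. Defaults by extension
#'   (`.json`; `.ttl`; `.rdf`/`.owl`/`.xml`).
#' @return a [knowledge_base()].
#' @export
load_kb <- function(path, format = c("auto", "json", "turtle", "rdfxml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     json = "json", ttl = "turtle", turtle = "turtle",
                     rdf = "rdfxml", owl = "rdfxml", xml = "rdfxml",
                     stop("cannot infer format from extension of ", path,
                          call. = FALSE))
  }
  switch(format,
         json = load_kb_json(path),
         turtle = load_kb_turtle(path),
         rdfxml = load_kb_rdfxml(path))
}

load_kb_json <- function(path) {
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop("parse error in ", path, ": ", conditionMessage(e),
                             call. = FALSE))
  if (!is.list(doc)) stop("parse error in ", path, ": top level must be an object",
                          call. = FALSE)
  for (k in intersect(names(doc), c("concepts", "properties", "rules")))
    if (!is.list(doc[[k]]))
      stop("parse error in ", path, ": '", k, "' must be an array", call. = FALSE)
  rules <- lapply(doc$rules %||% list(), function(r) {
    atom <- function(a) rule_atom(a$pred, a$kind, unlist(a$args))
    kb_rule(r$id, r$defines, lapply(r$body %||% list(), atom),
            lapply(r$head %||% list(), atom))
  })
  knowledge_base(concepts = doc$concepts %||% list(),
                 properties = doc$properties %||% list(),
                 rules = rules)
}

#' Serialize a knowledge base to the JSON dialect
#'
#' Round-trips: `load_kb(write_kb(kb, f))` reproduces an identical
#' knowledge base.
#'
#' @param kb a [knowledge_base()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_kb <- function(kb, path) {
  doc <- list(
    concepts = lapply(unname(kb$concepts), function(co)
      list(id = co$id, label = co$label, parents = as.list(co$parents))),
    properties = lapply(unname(kb$properties), function(pr) {
      o <- list(id = pr$id, label = pr$label, kind = pr$kind)
      if (length(pr$parents)) o$parents <- as.list(pr$parents)
      o
    }),
    rules = lapply(unname(kb$rules), function(r)
      list(id = r$id, defines = r$defines,
           body = lapply(r$body, atom_to_json),
           head = lapply(r$head, atom_to_json)))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

atom_to_json <- function(a)
  list(pred = a$pred, kind = a$kind, args = as.list(a$args))

# --- optional hierarchy-only imports -------------------------------------

RDFS_LABEL <- "http://www.w3.org/2000/01/rdf-schema#label"
RDFS_SUBCLASS <- "http://www.w3.org/2000/01/rdf-schema#subClassOf"

load_kb_rdfxml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("parse error in ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  ns <- c(rdf = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
          rdfs = "http://www.w3.org/2000/01/rdf-schema#",
          owl = "http://www.w3.org/2002/07/owl#")
  nodes <- xml2::xml_find_all(doc, "//owl:Class | //rdfs:Class | //rdf:Description",
                              ns = ns)
  concepts <- list()
  for (nd in nodes) {
    about <- xml2::xml_attr(nd, "rdf:about", ns = ns)
    if (is.na(about)) next
    label <- xml2::xml_text(xml2::xml_find_first(nd, "./rdfs:label", ns = ns))
    parents <- xml2::xml_attr(
      xml2::xml_find_all(nd, "./rdfs:subClassOf", ns = ns), "rdf:resource",
      ns = ns)
    parents <- parents[!is.na(parents)]
    id <- strip_iri(about)
    prev <- concepts[[id]]
    concepts[[id]] <- list(
      id = id,
      label = if (!is.na(label) && nzchar(label)) label else
        (prev$label %||% local_name(about)),
      parents = union(prev$parents %||% character(0), strip_iri(parents)))
  }
  knowledge_base(concepts = unname(concepts))
}

strip_iri <- function(x) sub("^.*[#/]", "", x)
local_name <- function(x) gsub("_", " ", strip_iri(x))

# Minimal Turtle subset: @prefix declarations; triples over rdfs:subClassOf
# and rdfs:label, with ';' predicate lists. Enough for hierarchy import;
# full Turtle is out of scope.
load_kb_turtle <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  prefixes <- list()
  concepts <- list()
  # join statements: a statement ends with '.'
  text <- paste(sub("^\\s*#.*$", "", lines), collapse = "\n")
  stmts <- strsplit(text, "(?<=\\.)\\s*\\n|\\.\\s*(?=\\n|$)", perl = TRUE)[[1]]
  stmts <- trimws(gsub("\\s+", " ", stmts))
  stmts <- stmts[nzchar(stmts)]
  for (i in seq_along(stmts)) {
    st <- sub("\\.$", "", stmts[[i]])
    st <- trimws(st)
    if (grepl("^@prefix", st)) {
      m <- regmatches(st, regexec("^@prefix\\s+([A-Za-z0-9_-]*):\\s+<([^>]*)>", st))[[1]]
      if (length(m) != 3)
        stop("parse error in ", path, " (statement ", i, "): bad @prefix",
             call. = FALSE)
      prefixes[[m[2]]] <- m[3]
      next
    }
    toks <- turtle_tokens(st)
    if (length(toks) < 3)
      stop("parse error in ", path, " (statement ", i, "): expected triple",
           call. = FALSE)
    subj <- turtle_expand(toks[1], prefixes)
    j <- 2L
    while (j + 1L <= length(toks)) {
      pred <- turtle_expand(toks[j], prefixes)
      obj <- toks[j + 1L]
      id <- strip_iri(subj)
      prev <- concepts[[id]] %||% list(id = id, label = local_name(subj),
                                       parents = character(0))
      if (pred == RDFS_SUBCLASS) {
        prev$parents <- union(prev$parents, strip_iri(turtle_expand(obj, prefixes)))
      } else if (pred == RDFS_LABEL) {
        prev$label <- gsub('^"|"(@[A-Za-z-]+)?$', "", obj)
      }
      concepts[[id]] <- prev
      j <- j + 2L
      if (j <= length(toks) && toks[j] == ";") j <- j + 1L else break
    }
  }
  knowledge_base(concepts = unname(concepts))
}

turtle_tokens <- function(st) {
  # split on spaces outside quotes and angle brackets
  m <- gregexpr('"[^"]*"(@[A-Za-z-]+)?|<[^>]*>|[^" ;]+|;', st)[[1]]
  regmatches(st, list(m))[[1]]
}

turtle_expand <- function(tok, prefixes) {
  if (startsWith(tok, "<")) return(gsub("^<|>$", "", tok))
  if (tok == "a") return("http://www.w3.org/1999/02/22-rdf-syntax-ns#type")
  parts <- strsplit(tok, ":", fixed = TRUE)[[1]]
  if (length(parts) == 2 && !is.null(prefixes[[parts[1]]]))
    return(paste0(prefixes[[parts[1]]], parts[2]))
  tok
}

# --- hierarchy metrics ----------------------------------------------------

check_concept <- function(kb, id) {
  if (!id %in% names(kb$concepts))
    stop("unknown concept id: '", id, "'", call. = FALSE)
}

#' Shortest-path distance between two concepts
#'
#' Subclass links are treated as undirected edges, so ancestors, descendants
#' and collaterals (siblings, cousins) are all reachable. Distance is 0 for
#' a concept to itself and `Inf` when no path connects the two concepts.
#'
#' @param kb a [knowledge_base()].
#' @param c1,c2 concept ids.
#' @return nonnegative integer hop count, or `Inf`.
#' @export
shortest_path_distance <- function(kb, c1, c2) {
  check_concept(kb, c1); check_concept(kb, c2)
  if (c1 == c2) return(0)
  as.vector(igraph::distances(kb$graph, v = c1, to = c2))
}

#' Semantic similarity of two concepts in the class hierarchy
#'
#' Similarity halves with every hop separating the concepts:
#' `Sim(C1, C2) = 2^(-ShortestPath(C1, C2))`. Identical concepts score 1; an
#' immediate parent or child scores 0.5; disconnected concepts score 0.
#'
#' @inheritParams shortest_path_distance
#' @return a real in `[0, 1]`.
#' @export
semantic_similarity <- function(kb, c1, c2) {
  d <- shortest_path_distance(kb, c1, c2)
  if (is.infinite(d)) 0 else 2^(-d)
}

# --- edits used by the leave-one-out evaluation ---------------------------

#' Remove a rule from a knowledge base
#'
#' Pure: returns a modified copy; the input is untouched.
#' @param kb a [knowledge_base()].
#' @param rule_id id of the rule to drop.
#' @return a new [knowledge_base()].
#' @export
remove_rule <- function(kb, rule_id) {
  if (!rule_id %in% names(kb$rules))
    stop("unknown rule id: '", rule_id, "'", call. = FALSE)
  knowledge_base(concepts = unname(kb$concepts),
                 properties = unname(kb$properties),
                 rules = unname(kb$rules[setdiff(names(kb$rules), rule_id)]))
}

#' Remove a concept and all rules defining it
#'
#' Drops the hierarchy node; links through it disappear (children keep any
#' other parents). Pure: returns a modified copy.
#' @param kb a [knowledge_base()].
#' @param concept_id id of the concept to drop.
#' @return a new [knowledge_base()].
#' @export
remove_concept <- function(kb, concept_id) {
  check_concept(kb, concept_id)
  keep_rules <- Filter(function(r) r$defines != concept_id, kb$rules)
  concepts <- lapply(kb$concepts[setdiff(names(kb$concepts), concept_id)],
                     function(co) {
                       co$parents <- setdiff(co$parents, concept_id)
                       co
                     })
  knowledge_base(concepts = unname(concepts),
                 properties = unname(kb$properties),
                 rules = unname(keep_rules))
}
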