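#' Canonical syntactic signature of a rule
#'
#' Rules with the same structure — regardless of predicate names, variable
#' names, constants, or atom order — share a *signature*, usable as a
#' template when authoring a definition for a concept the knowledge base
#' does not yet contain. Atoms (body and head pooled) are grouped by their
#' subject (first argument); each atom maps to a type code (`C` class,
#' `O` object property, `D` data property, `B` builtin); codes are sorted
#' within a group, groups are sorted lexicographically, and the result is
#' concatenated as parenthesized groups, e.g. `"(B)(CD)"`. A rule that
#' classifies a subject and assigns it one data value therefore yields
#' `"(CD)"`.
#'
#' @param rule a [kb_rule()].
#' @param split_head_body if `TRUE`, body and head are canonicalized
#'   separately and joined as `"body->head"`.
#' @return a character scalar of class `rule_signature`.
#' @export
rule_signature <- function(rule, split_head_body = FALSE) {
  sig <- if (split_head_body)
    paste0(atom_groups_signature(rule$body), "->",
           atom_groups_signature(rule$head))
  else
    atom_groups_signature(c(rule$body, rule$head))
  structure(sig, class = "rule_signature")
}

atom_groups_signature <- function(atoms) {
  if (!length(atoms)) return("")
  code <- c(class = "C", object_property = "O", data_property = "D",
            builtin = "B")
  subj <- vapply(atoms, function(a) a$args[[1]], character(1))
  codes <- code[vapply(atoms, `[[`, character(1), "kind")]
  groups <- vapply(split(codes, subj), function(g)
    paste0(sort(g, method = "radix"), collapse = ""), character(1))
  groups <- sort(unname(groups), method = "radix")
  paste0("(", groups, ")", collapse = "")
}

#' @export
print.rule_signature <- function(x, ...) {
  cat("<rule_signature>", unclass(x), "\n")
  invisible(x)
}

#' Partition a rule base by signature
#'
#' @param kb a [knowledge_base()].
#' @param split_head_body passed to [rule_signature()].
#' @return a named list: signature string -> character vector of rule ids.
#'   Group sizes sum to the rule count (a true partition).
#' @export
signature_census <- function(kb, split_head_body = FALSE) {
  if (!length(kb$rules)) return(stats::setNames(list(), character(0)))
  sigs <- vapply(kb$rules, function(r)
    as.character(rule_signature(r, split_head_body)), character(1))
  groups <- split(names(kb$rules), sigs)
  groups <- groups[order(names(groups), method = "radix")]
  lapply(groups, unname)
}

#' Rank of the first rule bearing a target signature
#'
#' Scans a ranked result top-down for the first rule whose signature equals
#' any of the target signature(s).
#'
#' @param result a [rank_rules()] result.
#' @param kb the [knowledge_base()] the ranked rules live in.
#' @param target_signature a `rule_signature` (or character vector of
#'   signature strings — any match counts).
#' @param split_head_body passed to [rule_signature()].
#' @return a positive integer.
#' @export
template_rank <- function(result, kb, target_signature,
                          split_head_body = FALSE) {
  target <- as.character(target_signature)
  for (i in seq_len(nrow(result))) {
    r <- kb$rules[[result$rule_id[[i]]]]
    if (is.null(r)) next
    if (as.character(rule_signature(r, split_head_body)) %in% target)
      return(i)
  }
  stop("no ranked rule bears signature(s): ",
       paste(target, collapse = ", "), call. = FALSE)
}

#' Write per-rule signatures and the census as TSV
#'
#' @param kb a [knowledge_base()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_signature_census <- function(kb, path) {
  census <- signature_census(kb)
  out <- data.frame(
    signature = names(census),
    count = vapply(census, length, integer(1)),
    rule_ids = vapply(census, paste, character(1), collapse = ","))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
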