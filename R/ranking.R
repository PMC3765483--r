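#' Cosine similarity of two term vectors
#'
#' Dot product over the union vocabulary divided by the product of the
#' Euclidean norms. All stored weights are nonnegative, so the score lies in
#' `[0, 1]`: 0 for orthogonal (no shared terms) and 1 for parallel vectors.
#' By contract an empty vector scores 0 against anything rather than raising
#' a division-by-zero error.
#'
#' @param a,b [term_vector()]s (named numeric vectors).
#' @return a real in `[0, 1]`.
#' @export
cosine <- function(a, b) {
  if (!length(a) || !length(b)) return(0)
  shared <- intersect(names(a), names(b))
  if (!length(shared)) return(0)
  num <- sum(as.numeric(a[shared]) * as.numeric(b[shared]))
  # single square root of the product keeps identical vectors at exactly 1
  min(1, num / sqrt(sum(as.numeric(a)^2) * sum(as.numeric(b)^2)))
}

#' Rank a rule base against a snippet
#'
#' Scores every rule vector by cosine similarity against the snippet's
#' tf-idf vector and sorts descending; ties are broken by ascending rule id
#' (C-locale lexicographic), so re-running is byte-identical.
#'
#' @param snip a [snippet()] in `corpus`, or its id.
#' @param corpus a [snippet_corpus][build_corpus()].
#' @param rule_vectors nonempty named list of [term_vector()]s keyed by
#'   rule id (see [vectorize_rulebase()]).
#' @param method label recorded in the result (e.g. `"semantic"`).
#' @return an object of class `ranked_result`: a data frame with columns
#'   `rank`, `rule_id`, `score`, plus attribute `method`.
#' @export
rank_rules <- function(snip, corpus, rule_vectors, method = "unspecified") {
  if (!length(rule_vectors))
    stop("rule_vectors is empty: nothing to rank", call. = FALSE)
  stopifnot(!is.null(names(rule_vectors)))
  sv <- tfidf_vector(snip, corpus)
  scores <- vapply(rule_vectors, cosine, numeric(1), b = sv)
  ord <- order(-scores, names(rule_vectors), method = "radix")
  res <- data.frame(rank = seq_along(ord),
                    rule_id = names(rule_vectors)[ord],
                    score = unname(scores[ord]))
  structure(res, class = c("ranked_result", "data.frame"), method = method)
}

#' @export
print.ranked_result <- function(x, n = 10L, ...) {
  cat("<ranked_result> method:", attr(x, "method"), "—", nrow(x), "rules\n")
  y <- utils::head(as.data.frame(x), n)
  y$score <- sprintf("%.6f", y$score)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Rank of the best-placed target rule
#'
#' A concept may be defined by several alternative rules; any of them is a
#' correct answer, so the rank of a target set is the minimum 1-based
#' position among its members.
#'
#' @param target_rule_ids character vector of rule ids.
#' @param result a [rank_rules()] result.
#' @return a positive integer.
#' @export
rank_of <- function(target_rule_ids, result) {
  pos <- match(target_rule_ids, result$rule_id)
  pos <- pos[!is.na(pos)]
  if (!length(pos))
    stop("none of the target rule(s) [",
         paste(target_rule_ids, collapse = ", "), "] appear in the ranking",
         call. = FALSE)
  min(pos)
}

#' Write a ranking as TSV or JSON
#'
#' Columns/fields: `rank`, `rule_id`, `concept_id`, `score` (6 decimal
#' places), `method`.
#'
#' @param result a [rank_rules()] result.
#' @param kb the [knowledge_base()] the rules came from (for `concept_id`).
#' @param path output path; format chosen by extension (`.json` vs TSV).
#' @return `path`, invisibly.
#' @export
write_ranking <- function(result, kb, path) {
  out <- data.frame(
    rank = result$rank,
    rule_id = result$rule_id,
    concept_id = vapply(result$rule_id, function(id)
      kb$rules[[id]]$defines %||% NA_character_, character(1)),
    score = sprintf("%.6f", result$score),
    method = attr(result, "method"))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(out, path, dataframe = "rows", pretty = TRUE)
  } else {
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
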