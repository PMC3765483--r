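#' Gold annotations
#'
#' An annotation links a snippet to a concept it defines and to the encoded
#' rule(s) experts associated with that definition. Stored as a data frame
#' with a list-column of rule ids; read and written as JSONL records
#' `{"snippet_id", "concept_id", "rule_ids": [...]}`.
#'
#' @param snippet_id,concept_id character vectors of equal length.
#' @param rule_ids list of character vectors, one per annotation.
#' @return a data frame of class `gold_annotations`.
#' @export
gold_annotations <- function(snippet_id, concept_id, rule_ids) {
  stopifnot(length(snippet_id) == length(concept_id),
            length(snippet_id) == length(rule_ids))
  key <- paste(snippet_id, concept_id)
  dup <- unique(key[duplicated(key)])
  if (length(dup))
    stop("duplicate (snippet_id, concept_id) pair(s): ",
         paste(dup, collapse = "; "), call. = FALSE)
  g <- data.frame(snippet_id = as.character(snippet_id),
                  concept_id = as.character(concept_id))
  g$rule_ids <- lapply(rule_ids, as.character)
  structure(g, class = c("gold_annotations", "data.frame"))
}

#' @rdname gold_annotations
#' @param path a JSONL file.
#' @export
read_gold <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  recs <- lapply(seq_along(lines), function(i)
    tryCatch(jsonlite::fromJSON(lines[[i]]),
             error = function(e) stop("parse error in ", path, " line ", i,
                                      ": ", conditionMessage(e), call. = FALSE)))
  gold_annotations(vapply(recs, `[[`, character(1), "snippet_id"),
                   vapply(recs, `[[`, character(1), "concept_id"),
                   lapply(recs, `[[`, "rule_ids"))
}

#' @rdname gold_annotations
#' @param gold a `gold_annotations` object.
#' @export
write_gold <- function(gold, path) {
  lines <- vapply(seq_len(nrow(gold)), function(i)
    jsonlite::toJSON(list(snippet_id = gold$snippet_id[[i]],
                          concept_id = gold$concept_id[[i]],
                          rule_ids = gold$rule_ids[[i]]),
                     auto_unbox = TRUE), character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

validate_gold <- function(gold, kb, corpus) {
  bad <- character(0)
  for (i in seq_len(nrow(gold))) {
    if (!gold$snippet_id[[i]] %in% names(corpus$snippets))
      bad <- c(bad, paste0("snippet '", gold$snippet_id[[i]], "'"))
    if (!gold$concept_id[[i]] %in% names(kb$concepts))
      bad <- c(bad, paste0("concept '", gold$concept_id[[i]], "'"))
    miss <- setdiff(gold$rule_ids[[i]], names(kb$rules))
    if (length(miss)) bad <- c(bad, paste0("rule '", miss, "'"))
  }
  if (length(bad))
    stop("gold annotations reference unknown ids: ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

# --- Wilcoxon signed-rank -------------------------------------------------

#' Paired Wilcoxon signed-rank test
#'
#' Compares two methods' per-item ranks through their paired differences.
#' Zero differences are dropped (Wilcoxon's convention); tied absolute
#' differences receive mid-ranks. The statistic is `V`, the sum of the
#' ranks of the positive differences. For `n <= 25` retained pairs the
#' two-sided p-value comes from the *exact* null distribution of `V` under
#' independent sign flips — computed by a generating-function convolution
#' over the (doubled, hence integer) mid-ranks, so it is exact even with
#' ties. Larger samples use the normal approximation with tie correction
#' and continuity correction.
#'
#' @param differences numeric vector of paired differences.
#' @param exact_max largest `n` for which the exact distribution is used.
#' @return a list with `statistic` (V), `p_value`, `n` (nonzero pairs) and
#'   `method` (`"exact"` or `"normal_approximation"`).
#' @export
wilcoxon_signed_rank <- function(differences, exact_max = 25L) {
  d <- differences[differences != 0]
  if (!length(d))
    stop("all paired differences are zero: the signed-rank test is undefined",
         call. = FALSE)
  n <- length(d)
  r <- rank(abs(d))          # mid-ranks for ties
  v <- sum(r[d > 0])
  if (n <= exact_max) {
    # doubled mid-ranks are integers; distribution of 2V by convolution
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    f <- numeric(total + 1L)  # f[s+1] = #assignments with doubled sum s
    f[1L] <- 1
    for (w in r2) {
      shifted <- c(numeric(w), f[seq_len(total + 1L - w)])
      f <- f + shifted
    }
    f <- f / 2^n
    v2 <- as.integer(round(2 * v))
    p_le <- sum(f[seq_len(v2 + 1L)])
    p_ge <- sum(f[seq.int(v2 + 1L, total + 1L)])
    p <- min(1, 2 * min(p_le, p_ge))
    list(statistic = v, p_value = p, n = n, method = "exact")
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- v - mu
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)  # continuity correction
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    list(statistic = v, p_value = p, n = n, method = "normal_approximation")
  }
}

# --- evaluation report ----------------------------------------------------

new_report <- function(scenario, ranks_sem, ranks_term, excluded = 0L) {
  stopifnot(identical(names(ranks_sem), names(ranks_term)))
  if (!length(ranks_sem))
    stop("no evaluable items for scenario '", scenario, "'", call. = FALSE)
  diffs <- ranks_term - ranks_sem   # positive = semantic placed better
  wt <- if (any(diffs != 0)) wilcoxon_signed_rank(diffs) else
    list(statistic = NA_real_, p_value = NA_real_, n = 0L, method = "degenerate")
  structure(list(
    scenario = scenario,
    per_item_ranks = list(semantic = ranks_sem, term_based = ranks_term),
    average_rank = c(semantic = mean(ranks_sem), term_based = mean(ranks_term)),
    pairwise_mean_difference = mean(diffs),
    pairwise_mean_abs_difference = mean(abs(diffs)),
    wilcoxon_statistic = wt$statistic,
    p_value = wt$p_value,
    wilcoxon_method = wt$method,
    n_items = length(ranks_sem),
    n_excluded = as.integer(excluded)),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report> scenario:", x$scenario, "—", x$n_items, "items")
  if (x$n_excluded) cat(" (", x$n_excluded, " excluded)", sep = "")
  cat("\n  average rank   semantic:",
      sprintf("%.3f", x$average_rank[["semantic"]]),
      "  term-based:", sprintf("%.3f", x$average_rank[["term_based"]]), "\n")
  cat("  mean paired difference (term - semantic):",
      sprintf("%.3f", x$pairwise_mean_difference),
      " |.|:", sprintf("%.3f", x$pairwise_mean_abs_difference), "\n")
  cat("  Wilcoxon V =", x$wilcoxon_statistic,
      " p =", format(x$p_value, digits = 4),
      paste0("(", x$wilcoxon_method, ")"), "\n")
  invisible(x)
}

report_to_list <- function(x) {
  list(scenario = x$scenario,
       n_items = x$n_items,
       n_excluded = x$n_excluded,
       average_rank = as.list(x$average_rank),
       pairwise_mean_difference = x$pairwise_mean_difference,
       pairwise_mean_abs_difference = x$pairwise_mean_abs_difference,
       wilcoxon_statistic = x$wilcoxon_statistic,
       p_value = x$p_value,
       wilcoxon_method = x$wilcoxon_method,
       per_item_ranks = list(
         semantic = as.list(x$per_item_ranks$semantic),
         term_based = as.list(x$per_item_ranks$term_based)))
}

#' Write an evaluation report as JSON and TSV
#'
#' @param report an `evaluation_report`.
#' @param stem output path stem; writes `<stem>.json` and `<stem>.tsv`.
#' @return the stem, invisibly.
#' @export
write_report <- function(report, stem) {
  jsonlite::write_json(report_to_list(report), paste0(stem, ".json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  items <- data.frame(item = names(report$per_item_ranks$semantic),
                      semantic = unname(report$per_item_ranks$semantic),
                      term_based = unname(report$per_item_ranks$term_based))
  utils::write.table(items, paste0(stem, ".tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(stem)
}

# --- scenarios ------------------------------------------------------------

method_configs <- function(sem_config, term_config) {
  stopifnot(sem_config$method == "semantic", term_config$method == "term_based")
  list(semantic = sem_config, term_based = term_config)
}

#' Scenario 1: the snippet's definition is already encoded
#'
#' For every gold (snippet, concept) pair, all rules are ranked against the
#' snippet with both vectorization methods and the position of the
#' best-placed gold rule is recorded; per-method averages and the paired
#' Wilcoxon comparison summarize the run.
#'
#' @param kb a [knowledge_base()].
#' @param corpus a [snippet_corpus][build_corpus()].
#' @param gold [gold_annotations()].
#' @param sem_config a semantic [vectorizer_config()].
#' @param term_config a term-based [vectorizer_config()].
#' @return an `evaluation_report`.
#' @export
evaluate_scenario1 <- function(kb, corpus, gold,
                               sem_config = vectorizer_config("semantic"),
                               term_config = vectorizer_config("term_based")) {
  validate_gold(gold, kb, corpus)
  cfgs <- method_configs(sem_config, term_config)
  ranks <- list()
  for (m in names(cfgs)) {
    vecs <- vectorize_rulebase(kb, cfgs[[m]])
    rankings <- list()   # one ranking per snippet, reused across concepts
    rk <- numeric(nrow(gold))
    for (i in seq_len(nrow(gold))) {
      sid <- gold$snippet_id[[i]]
      if (is.null(rankings[[sid]]))
        rankings[[sid]] <- rank_rules(sid, corpus, vecs, m)
      rk[[i]] <- rank_of(gold$rule_ids[[i]], rankings[[sid]])
    }
    ranks[[m]] <- stats::setNames(rk, paste(gold$snippet_id, gold$concept_id,
                                            sep = "|"))
  }
  new_report("existing", ranks$semantic, ranks$term_based)
}

#' Scenario 2: the snippet defines an alternative to an encoded rule
#'
#' For each gold concept holding at least two rules, each of its rules is
#' removed in turn; the surviving *alternative* rules of the same concept
#' are then searched for in the ranking of the reduced rule base against
#' each gold snippet of that concept. Items are keyed
#' `snippet|concept|removed_rule`.
#'
#' @inheritParams evaluate_scenario1
#' @return an `evaluation_report`.
#' @export
evaluate_scenario2 <- function(kb, corpus, gold,
                               sem_config = vectorizer_config("semantic"),
                               term_config = vectorizer_config("term_based")) {
  validate_gold(gold, kb, corpus)
  cfgs <- method_configs(sem_config, term_config)
  multi <- names(kb$rules_by_concept)[
    vapply(kb$rules_by_concept, length, integer(1)) >= 2L]
  items <- gold[gold$concept_id %in% multi, , drop = FALSE]
  if (!nrow(items))
    stop("scenario 2 requires gold concepts with at least 2 rule definitions",
         call. = FALSE)
  ranks <- list()
  for (m in names(cfgs)) {
    # removing a rule leaves the hierarchy - and hence every other rule's
    # vector - unchanged, so vectors are computed once and subset per item;
    # tests verify equality against a naive rebuild-per-removal
    vecs <- vectorize_rulebase(kb, cfgs[[m]])
    rk <- numeric(0)
    for (i in seq_len(nrow(items))) {
      cid <- items$concept_id[[i]]
      sid <- items$snippet_id[[i]]
      for (removed in kb$rules_by_concept[[cid]]) {
        res <- rank_rules(sid, corpus,
                          vecs[setdiff(names(vecs), removed)], m)
        alternatives <- setdiff(kb$rules_by_concept[[cid]], removed)
        rk[[paste(sid, cid, removed, sep = "|")]] <-
          rank_of(alternatives, res)
      }
    }
    ranks[[m]] <- rk
  }
  new_report("alternative", ranks$semantic, ranks$term_based)
}

#' Scenario 3: the snippet defines a concept absent from the knowledge base
#'
#' For each gold (snippet, concept) pair the concept and all of its rules
#' are deleted; the remaining rules are ranked against the snippet and the
#' position of the first rule bearing the deleted rules' syntactic
#' signature ([rule_signature()]) is recorded. Items whose signature
#' survives on no remaining rule cannot be scored; they are excluded and
#' counted (identically for both methods, so pairing is preserved).
#'
#' @inheritParams evaluate_scenario1
#' @return an `evaluation_report`.
#' @export
evaluate_scenario3 <- function(kb, corpus, gold,
                               sem_config = vectorizer_config("semantic"),
                               term_config = vectorizer_config("term_based")) {
  validate_gold(gold, kb, corpus)
  cfgs <- method_configs(sem_config, term_config)
  defined <- names(kb$rules_by_concept)
  if (length(defined) < 2L)
    stop("scenario 3 requires at least 2 concepts with rules", call. = FALSE)
  items <- gold[gold$concept_id %in% defined, , drop = FALSE]
  ranks <- list(semantic = numeric(0), term_based = numeric(0))
  excluded <- 0L
  for (i in seq_len(nrow(items))) {
    cid <- items$concept_id[[i]]
    sid <- items$snippet_id[[i]]
    target_sigs <- unique(vapply(kb$rules_by_concept[[cid]], function(rid)
      as.character(rule_signature(kb$rules[[rid]])), character(1)))
    kb2 <- remove_concept(kb, cid)
    surviving_sigs <- names(signature_census(kb2))
    if (!any(target_sigs %in% surviving_sigs)) {
      excluded <- excluded + 1L
      next
    }
    key <- paste(sid, cid, sep = "|")
    for (m in names(cfgs)) {
      vecs <- vectorize_rulebase(kb2, cfgs[[m]])
      res <- rank_rules(sid, corpus, vecs, m)
      ranks[[m]][[key]] <- template_rank(res, kb2, target_sigs)
    }
  }
  new_report("template", ranks$semantic, ranks$term_based, excluded = excluded)
}
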