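#' Term vectors
#'
#' A term vector is the common sparse representation for both snippets and
#' rules: a named numeric vector mapping terms to strictly positive finite
#' weights. Zero and negative entries are pruned at construction;
#' contributions with duplicate names are summed; names are sorted so that
#' equal vectors are byte-identical.
#'
#' @param weights a named numeric vector (possibly with repeated names).
#' @return a named numeric vector of class `term_vector`.
#' @export
term_vector <- function(weights = numeric(0)) {
  if (length(weights)) {
    stopifnot(!is.null(names(weights)), all(nzchar(names(weights))))
    if (any(!is.finite(weights)))
      stop("term weights must be finite", call. = FALSE)
    weights <- vapply(split(unname(weights), names(weights)), sum, numeric(1))
    weights <- weights[weights > 0]
    weights <- weights[order(names(weights), method = "radix")]
  }
  structure(as.numeric(weights), names = names(weights), class = "term_vector")
}

#' @export
print.term_vector <- function(x, ...) {
  cat("<term_vector>", length(x), "terms\n")
  if (length(x)) print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}

vector_norm <- function(v) sqrt(sum(as.numeric(v)^2))

#' Construct a snippet
#'
#' @param id snippet identifier (unique within a corpus).
#' @param text raw snippet text.
#' @param config a [tokenizer_config()]; tokens are populated eagerly.
#' @return a list of class `snippet` with fields `id`, `text`, `tokens`.
#' @export
snippet <- function(id, text, config = tokenizer_config()) {
  structure(list(id = as.character(id), text = as.character(text),
                 tokens = tokenize(as.character(text), config)),
            class = "snippet")
}

#' Build a corpus from snippets
#'
#' Computes the corpus size `n` and the document-frequency table `df`:
#' `df[t]` counts the snippets *containing* term `t` (presence, not
#' occurrences), so `1 <= df[t] <= n` for every indexed term.
#'
#' @param snippets list of [snippet()]s, or a character vector of raw texts
#'   (ids are then `s1`, `s2`, ...).
#' @param config a [tokenizer_config()] used for any raw texts.
#' @return an object of class `snippet_corpus` with elements `snippets`
#'   (named list keyed by id), `n` and `df` (named integer vector).
#' @export
build_corpus <- function(snippets, config = tokenizer_config()) {
  if (is.character(snippets))
    snippets <- lapply(seq_along(snippets), function(i)
      snippet(paste0("s", i), snippets[[i]], config))
  snippets <- lapply(snippets, function(s) {
    if (inherits(s, "snippet")) s else snippet(s$id, s$text, config)
  })
  ids <- vapply(snippets, `[[`, character(1), "id")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate snippet id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  names(snippets) <- ids
  present <- unlist(lapply(snippets, function(s) unique(s$tokens)),
                    use.names = FALSE)
  df <- table(if (is.null(present)) character(0) else present)
  df <- stats::setNames(as.integer(df), names(df))
  if (length(df)) df <- df[order(names(df), method = "radix")]
  structure(list(snippets = snippets, n = length(snippets), df = df),
            class = "snippet_corpus")
}

#' @export
print.snippet_corpus <- function(x, ...) {
  cat("<snippet_corpus>", x$n, "snippets,", length(x$df), "distinct terms\n")
  invisible(x)
}

#' Read snippets from JSONL or a directory of text files
#'
#' JSONL input has one object per line with fields `id` and `text`. A
#' directory is read as one snippet per `*.txt` file, the filename stem
#' being the id.
#'
#' @param path a `.jsonl` file or a directory.
#' @param config a [tokenizer_config()].
#' @return a [build_corpus()] result.
#' @export
read_snippets <- function(path, config = tokenizer_config()) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.txt$", full.names = TRUE))
    if (!length(files)) stop("no .txt files in ", path, call. = FALSE)
    sn <- lapply(files, function(f)
      snippet(tools::file_path_sans_ext(basename(f)),
              paste(readLines(f, warn = FALSE, encoding = "UTF-8"),
                    collapse = "\n"),
              config))
    return(build_corpus(sn, config))
  }
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  sn <- lapply(seq_along(lines), function(i) {
    rec <- tryCatch(jsonlite::fromJSON(lines[[i]]),
                    error = function(e) stop("parse error in ", path, " line ",
                                             i, ": ", conditionMessage(e),
                                             call. = FALSE))
    if (is.null(rec$id) || is.null(rec$text))
      stop("parse error in ", path, " line ", i, ": need fields id, text",
           call. = FALSE)
    snippet(rec$id, rec$text, config)
  })
  build_corpus(sn, config)
}

#' tf-idf vector of a snippet within its corpus
#'
#' The weight of term `i` in snippet `d` is `tf_[i,d] * log10(n / df_i)`,
#' where `tf` is the raw count of the term in the snippet, `n` the number of
#' snippets in the corpus and `df_i` the number of snippets containing the
#' term. A term present in every snippet gets idf 0 and is pruned.
#'
#' @param snip a [snippet()] belonging to `corpus` (every token must be in
#'   the document-frequency table).
#' @param corpus a [snippet_corpus][build_corpus()].
#' @return a [term_vector()].
#' @export
tfidf_vector <- function(snip, corpus) {
  if (is.character(snip) && length(snip) == 1L) {
    if (!snip %in% names(corpus$snippets))
      stop("unknown snippet id: '", snip, "'", call. = FALSE)
    snip <- corpus$snippets[[snip]]
  }
  toks <- snip$tokens
  if (!length(toks)) return(term_vector())
  tf <- table(toks)
  missing <- setdiff(names(tf), names(corpus$df))
  if (length(missing))
    stop("snippet '", snip$id, "' has term(s) absent from the corpus ",
         "document-frequency table: ", paste(missing, collapse = ", "),
         call. = FALSE)
  w <- as.numeric(tf) * log10(corpus$n / as.numeric(corpus$df[names(tf)]))
  term_vector(stats::setNames(w, names(tf)))
}
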