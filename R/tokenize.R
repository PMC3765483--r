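#' Tokenizer configuration
#'
#' Controls how raw text (snippets, concept labels, property labels) is
#' normalized into terms. The same configuration must be used for the
#' snippet corpus and the rule vectors so that their vocabularies align.
#'
#' @param stopwords character vector of stopwords, or a path to a plain-text
#'   file with one word per line. `NULL` uses the packaged English list.
#' @param stemming must be `FALSE`; suffix stemming is not implemented.
#' @param min_token_len minimum token length kept (default 1, so single
#'   letters such as the "R" of "ADI-R" survive).
#' @param keep_numbers keep purely numeric tokens (default `TRUE`: numeric
#'   cut-offs like "24" are the informative content of threshold rules).
#' @return a list of class `tokenizer_config`.
#' @export
tokenizer_config <- function(stopwords = NULL, stemming = FALSE,
                             min_token_len = 1L, keep_numbers = TRUE) {
  if (isTRUE(stemming))
    stop("stemming is not implemented; set stemming = FALSE", call. = FALSE)
  if (is.null(stopwords)) {
    stopwords <- default_stopwords()
  } else if (is.character(stopwords) && length(stopwords) == 1L &&
             file.exists(stopwords)) {
    stopwords <- readLines(stopwords, warn = FALSE, encoding = "UTF-8")
  }
  stopwords <- tolower(trimws(stopwords))
  stopwords <- stopwords[nzchar(stopwords)]
  structure(list(stopwords = stopwords, stemming = FALSE,
                 min_token_len = as.integer(min_token_len),
                 keep_numbers = isTRUE(keep_numbers)),
            class = "tokenizer_config")
}

default_stopwords <- function() {
  path <- system.file("extdata", "stopwords_en.txt", package = "ontorank")
  readLines(path, warn = FALSE, encoding = "UTF-8")
}

#' Normalize text into an ordered list of terms
#'
#' Splitting happens on every non-alphanumeric character (hyphens and
#' underscores included) and at lowercase-to-uppercase camel-case boundaries
#' ("StatusOfAgeOfWords" -> status, age, words after stopword removal).
#' Terms are lowercased; stopwords and empty fragments are dropped; numeric
#' tokens are kept by default. Total and deterministic: any string, including
#' the empty one, yields a (possibly empty) token vector.
#'
#' @param text a character scalar.
#' @param config a [tokenizer_config()].
#' @return character vector of terms, in order of appearance.
#' @export
tokenize <- function(text, config = tokenizer_config()) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(text)) return(character(0))
  # camel-case boundaries become spaces before lowercasing
  text <- gsub("([a-z0-9])([A-Z])", "\\1 \\2", text)
  toks <- strsplit(tolower(text), "[^a-z0-9]+")[[1]]
  toks <- toks[nzchar(toks)]
  toks <- toks[nchar(toks) >= config$min_token_len]
  if (!config$keep_numbers) toks <- toks[!grepl("^[0-9]+$", toks)]
  toks[!toks %in% config$stopwords]
}
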