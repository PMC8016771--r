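#' English stop-word list shipped with the package
#'
#' Stop words are *marked*, never deleted, during preparation: downstream
#' stages need original token adjacency (phrase candidates may contain
#' interior stop words but may not start or end with one), so deletion
#' decisions belong to the TF-IDF and phrase-extraction stages.
#'
#' @return Character vector of lower-case stop words.
#' @export
stopwords_en <- function() {
  path <- system.file("extdata", "stopwords_en.txt", package = "endovoices")
  readLines(path, encoding = "UTF-8")
}

# small irregular-form table; the rule-based lemmatiser falls back to
# suffix stripping (plurals, -ing, -ed) for everything else
.irregular_lemmas <- c(
  children = "child", feet = "foot", teeth = "tooth", women = "woman",
  men = "man", mice = "mouse", people = "person", crises = "crisis",
  diagnoses = "diagnosis", analyses = "analysis", lives = "life",
  worse = "bad", worst = "bad", better = "good", best = "good",
  felt = "feel", slept = "sleep", kept = "keep", left = "leave",
  took = "take", taken = "take", gave = "give", given = "give",
  went = "go", gone = "go", made = "make", said = "say", found = "find",
  thought = "think", knew = "know", known = "know", lost = "lose"
)

# words a naive suffix rule would mangle
.lemma_exceptions <- c(
  "this", "his", "its", "is", "was", "has", "does", "yes", "less",
  "stress", "illness", "tiredness", "weakness", "loss", "process",
  "access", "thing", "nothing", "something", "everything", "morning",
  "evening", "during", "being", "crisis", "diagnosis", "analysis",
  "diabetes", "news", "always", "perhaps", "sometimes", "besides",
  "series", "species", "as", "us", "gas", "plus", "versus", "virus",
  "focus", "status", "bonus", "used", "need", "bed", "red", "tired"
)

lemmatize_token <- function(token) {
  if (token %in% names(.irregular_lemmas)) return(unname(.irregular_lemmas[token]))
  if (token %in% .lemma_exceptions) return(token)
  n <- nchar(token)
  # present participle: sleeping -> sleep, running -> run
  if (n > 5 && endsWith(token, "ing")) {
    stem <- substr(token, 1, n - 3)
    m <- nchar(stem)
    if (m >= 3 && substr(stem, m, m) == substr(stem, m - 1, m - 1)) {
      stem <- substr(stem, 1, m - 1)          # doubled consonant
    }
    return(stem)
  }
  # past tense: treated -> treat, cared -> care is ambiguous; strip -ed only
  if (n > 4 && endsWith(token, "ed") && !endsWith(token, "eed")) {
    stem <- substr(token, 1, n - 2)
    m <- nchar(stem)
    if (m >= 3 && substr(stem, m, m) == substr(stem, m - 1, m - 1)) {
      stem <- substr(stem, 1, m - 1)
    }
    return(stem)
  }
  # plurals: apples -> apple, bodies -> body, crashes -> crash
  if (n > 3 && endsWith(token, "ies")) {
    return(paste0(substr(token, 1, n - 3), "y"))
  }
  if (n > 3 && (endsWith(token, "ses") || endsWith(token, "xes") ||
                endsWith(token, "zes") || endsWith(token, "ches") ||
                endsWith(token, "shes"))) {
    return(substr(token, 1, n - 2))
  }
  if (n > 2 && endsWith(token, "s") && !endsWith(token, "ss") &&
      !endsWith(token, "us") && !endsWith(token, "is")) {
    return(substr(token, 1, n - 1))
  }
  token
}

#' Tokenise and lemmatise a text
#'
#' Lower-cases, strips punctuation, splits on whitespace, reduces each word
#' to its dictionary form (a deterministic rule-based lemmatiser: plural and
#' participle suffix stripping plus a small irregular-form table, so that
#' e.g. "sleeping" becomes "sleep" and "apples" becomes "apple"), and marks
#' stop words without removing them. Numerals are retained as tokens
#' (dosage mentions can be numeric). Idempotent on its own output.
#'
#' @param text A character scalar (may be empty).
#' @return A list with `tokens` (character) and `stopword_mask` (logical,
#'   same length; `TRUE` marks a stop word).
#' @export
tokenize_lemmatize <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  if (is.na(text) || !nzchar(trimws(text))) {
    return(list(tokens = character(0), stopword_mask = logical(0)))
  }
  x <- tolower(text)
  x <- gsub("[^\\p{L}\\p{N}]+", " ", x, perl = TRUE)
  raw <- strsplit(trimws(x), "\\s+")[[1]]
  raw <- raw[nzchar(raw)]
  if (length(raw) == 0) {
    return(list(tokens = character(0), stopword_mask = logical(0)))
  }
  toks <- vapply(raw, lemmatize_token, character(1), USE.NAMES = FALSE)
  sw <- stopwords_en()
  mask <- raw %in% sw | toks %in% sw
  list(tokens = toks, stopword_mask = mask)
}

#' Identity translator
#'
#' The translation step is pluggable: a translator is a function mapping a
#' character vector to a character vector of equal length (an attribute
#' `"translator_name"` is used for provenance). The default is a bit-exact
#' pass-through, standing in for an external machine-translation service.
#'
#' @return A translator function.
#' @export
identity_translator <- function() {
  f <- function(x) x
  attr(f, "translator_name") <- "identity"
  f
}

#' Translate the raw text of a document set
#'
#' Applies the translator document-by-document. A document on which the
#' translator throws is retained untranslated and flagged in the
#' `translation_failed` column; documents are never silently dropped.
#'
#' @param documents Tibble with at least a `text` column.
#' @param translator A translator function (see [identity_translator()]).
#' @return `documents` with `text` replaced where translation succeeded,
#'   plus a `translation_failed` logical column; translator name recorded
#'   in the `"provenance"` attribute.
#' @export
translate_documents <- function(documents, translator = identity_translator()) {
  stopifnot(is.data.frame(documents), "text" %in% names(documents))
  out <- documents
  failed <- logical(nrow(documents))
  txt <- documents$text
  for (i in seq_along(txt)) {
    res <- tryCatch(translator(txt[[i]]), error = function(e) e)
    if (inherits(res, "error")) {
      failed[i] <- TRUE
    } else {
      txt[[i]] <- res
    }
  }
  out$text <- txt
  out$translation_failed <- failed
  attr(out, "provenance") <- list(
    translator = attr(translator, "translator_name") %||% "unnamed",
    n_failed = sum(failed))
  out
}

#' Prepare a document set for analysis
#'
#' Runs translation (identity by default) and tokenisation/lemmatisation,
#' adding `tokens` and `stopword_mask` list-columns. One row is one
#' document: one respondent's answer to one open question.
#'
#' @param documents Tibble with columns `respondent_id`, `question_id`,
#'   `mtg`, `text`.
#' @inheritParams translate_documents
#' @return The enriched document tibble (class `document_set`).
#' @export
prepare_documents <- function(documents, translator = identity_translator()) {
  req <- c("respondent_id", "question_id", "mtg", "text")
  missing_cols <- setdiff(req, names(documents))
  if (length(missing_cols) > 0) {
    schema_error(paste0("document set lacks column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  out <- translate_documents(documents, translator)
  tl <- lapply(out$text, tokenize_lemmatize)
  out$tokens <- lapply(tl, `[[`, "tokens")
  out$stopword_mask <- lapply(tl, `[[`, "stopword_mask")
  class(out) <- c("document_set", class(out))
  out
}

#' Pool the documents of several open questions into one analysis set
#'
#' Responses to the named questions are combined and weighted equally: each
#' response stays a distinct document, and respondent attribution is kept
#' (one respondent answering two questions contributes two documents with
#' the same `respondent_id`, which the per-respondent phrase de-duplication
#' downstream relies on).
#'
#' @param document_set A prepared document tibble.
#' @param question_ids Character vector of question ids to pool.
#' @return The subset of `document_set` for those questions.
#' @export
combine_questions <- function(document_set, question_ids) {
  present <- unique(document_set$question_id)
  unknown <- setdiff(question_ids, present)
  if (length(unknown) > 0) {
    config_error(paste0("unknown question id(s): ",
                        paste(unknown, collapse = ", ")),
                 field = "question_ids")
  }
  document_set[document_set$question_id %in% question_ids, , drop = FALSE]
}

#' Read / write a document set as JSON-lines
#'
#' One JSON object per line with fields `respondent_id`, `question_id`,
#' `mtg`, `text`.
#'
#' @param path File path.
#' @param documents Document tibble.
#' @return `read_documents_jsonl` returns a tibble; `write_documents_jsonl`
#'   returns `path` invisibly.
#' @export
read_documents_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  rows <- lapply(lines, jsonlite::fromJSON)
  tibble::tibble(
    respondent_id = vapply(rows, `[[`, character(1), "respondent_id"),
    question_id = vapply(rows, `[[`, character(1), "question_id"),
    mtg = vapply(rows, `[[`, character(1), "mtg"),
    text = vapply(rows, `[[`, character(1), "text"))
}

#' @rdname read_documents_jsonl
#' @export
write_documents_jsonl <- function(documents, path) {
  lines <- vapply(seq_len(nrow(documents)), function(i) {
    jsonlite::toJSON(list(
      respondent_id = documents$respondent_id[[i]],
      question_id = documents$question_id[[i]],
      mtg = documents$mtg[[i]],
      text = documents$text[[i]]), auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
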