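#' Build n-gram counts for a background corpus
#'
#' Tokenises and lemmatises each line (one document per line) and counts
#' all 1- to 4-gram occurrences within documents. The background corpus
#' approximates ordinary language; survey terms much more frequent in the
#' foreground than here are the informative ones.
#'
#' @param lines Character vector, one document per line; or a path to a
#'   UTF-8 plain-text file when `from_file = TRUE`.
#' @param from_file Read `lines` from disk.
#' @return A `background_corpus`: list of per-length count tables
#'   (`counts[[l]]` named integer vector), per-length occurrence totals
#'   `totals`, and `n_tokens`.
#' @export
background_corpus <- function(lines, from_file = FALSE) {
  if (from_file) lines <- readLines(lines, encoding = "UTF-8")
  token_lists <- lapply(lines, function(x) tokenize_lemmatize(x)$tokens)
  counts <- count_ngrams(token_lists, max_len = 4)
  structure(list(counts = counts$counts, totals = counts$totals,
                 n_tokens = sum(lengths(token_lists))),
            class = "background_corpus")
}

#' @export
print.background_corpus <- function(x, ...) {
  cat(sprintf("background corpus: %d tokens, %d distinct unigrams\n",
              x$n_tokens, length(x$counts[[1]])))
  invisible(x)
}

# counts all n-gram occurrences (no stop-word constraint here: these are
# the denominator language models; the constraint applies to candidates)
count_ngrams <- function(token_lists, max_len = 4) {
  counts <- vector("list", max_len)
  totals <- integer(max_len)
  grams <- vector("list", max_len)
  for (l in seq_len(max_len)) grams[[l]] <- list()
  for (tk in token_lists) {
    n <- length(tk)
    for (l in seq_len(max_len)) {
      if (n < l) next
      g <- vapply(seq_len(n - l + 1), function(s) {
        paste(tk[s:(s + l - 1)], collapse = " ")
      }, character(1))
      grams[[l]][[length(grams[[l]]) + 1]] <- g
      totals[l] <- totals[l] + length(g)
    }
  }
  for (l in seq_len(max_len)) {
    all_g <- unlist(grams[[l]])
    counts[[l]] <- if (length(all_g) > 0) {
      tbl <- table(all_g)
      setNames(as.integer(tbl), names(tbl))
    } else {
      setNames(integer(0), character(0))
    }
  }
  list(counts = counts, totals = totals)
}

#' Extract candidate phrases from a group's documents
#'
#' Enumerates every 1- to 4-gram occurrence within each response (an
#' occurrence never spans two responses), then enforces the candidate
#' constraints: a phrase may not start or end with a stop word (interior
#' stop words are allowed) and must occur at least twice in the group.
#' Punctuation is already absent after tokenisation.
#'
#' @param documents Prepared document tibble for one group (needs
#'   `tokens`, `stopword_mask`, `respondent_id`).
#' @param max_len Maximum phrase length in words.
#' @param min_count Minimum occurrence count.
#' @return Tibble of candidates: `phrase`, `length`, `fg_count`, and a
#'   list-column `respondents` holding the respondent id of every
#'   occurrence.
#' @export
extract_candidates <- function(documents, max_len = 4, min_count = 2) {
  if (nrow(documents) == 0) {
    return(tibble::tibble(phrase = character(0), length = integer(0),
                          fg_count = integer(0), respondents = list()))
  }
  occ_phrase <- character(0)
  occ_len <- integer(0)
  occ_resp <- character(0)
  for (i in seq_len(nrow(documents))) {
    tk <- documents$tokens[[i]]
    mask <- documents$stopword_mask[[i]]
    n <- length(tk)
    if (n == 0) next
    for (l in seq_len(max_len)) {
      if (n < l) next
      for (s in seq_len(n - l + 1)) {
        e <- s + l - 1
        if (mask[s] || mask[e]) next  # boundary stop-word rule
        occ_phrase <- c(occ_phrase, paste(tk[s:e], collapse = " "))
        occ_len <- c(occ_len, l)
        occ_resp <- c(occ_resp, documents$respondent_id[[i]])
      }
    }
  }
  if (length(occ_phrase) == 0) {
    return(tibble::tibble(phrase = character(0), length = integer(0),
                          fg_count = integer(0), respondents = list()))
  }
  by_phrase <- split(occ_resp, occ_phrase)
  out <- tibble::tibble(
    phrase = names(by_phrase),
    length = unname(lengths(strsplit(names(by_phrase), " ", fixed = TRUE))),
    fg_count = unname(lengths(by_phrase)),
    respondents = unname(by_phrase))
  out <- out[out$fg_count >= min_count, , drop = FALSE]
  out[order(out$phrase), , drop = FALSE]
}

#' Collapse repeated 3-4-grams of the same respondent
#'
#' Three- and four-word combinations occurring more than once in the
#' answers of the same person are counted once, so a single vocal
#' respondent cannot dominate the group's phrase ranking. One- and
#' two-word phrases are left unchanged. Phrases falling below the
#' minimum count after collapsing are dropped.
#'
#' @param candidates Tibble from [extract_candidates()].
#' @param min_count Minimum count kept after de-duplication.
#' @return De-duplicated candidate tibble.
#' @export
dedup_per_respondent <- function(candidates, min_count = 2) {
  if (nrow(candidates) == 0) return(candidates)
  out <- candidates
  long <- out$length >= 3
  out$fg_count[long] <- vapply(out$respondents[long], function(r) {
    length(unique(r))
  }, integer(1))
  out$respondents[long] <- lapply(out$respondents[long], unique)
  out[out$fg_count >= min_count, , drop = FALSE]
}

#' Add-alpha n-gram language model
#'
#' P(phrase) = (count + alpha) / (total + alpha * V), per phrase length,
#' where V is the vocabulary size for that length (the union of observed
#' n-grams, extensible with a fixed extra mass for unseen queries). With
#' alpha = 0 this is the maximum-likelihood estimate, invariant under
#' scaling all counts and totals by a constant; with alpha > 0 every
#' queried phrase has positive probability.
#'
#' @param counts List of per-length named count vectors (as in
#'   [background_corpus()]), or a single named vector (treated as
#'   length-stratified by the phrases' word counts).
#' @param totals Integer vector of per-length occurrence totals.
#' @param alpha Smoothing constant.
#' @param vocab_sizes Optional per-length V overriding the observed
#'   vocabulary size (used to share a smoothing floor between foreground
#'   and background).
#' @return A function `p(phrase)` returning the probability of a phrase
#'   (character scalar, words separated by spaces).
#' @export
build_lm <- function(counts, totals, alpha = 0, vocab_sizes = NULL) {
  stopifnot(is.list(counts), length(totals) >= length(counts))
  if (is.null(vocab_sizes)) vocab_sizes <- vapply(counts, length, integer(1))
  function(phrase) {
    l <- length(strsplit(phrase, " ", fixed = TRUE)[[1]])
    if (l > length(counts)) return(0)
    c_tbl <- counts[[l]]
    cnt <- if (phrase %in% names(c_tbl)) c_tbl[[phrase]] else 0
    denom <- totals[l] + alpha * vocab_sizes[l]
    if (denom == 0) return(0)
    (cnt + alpha) / denom
  }
}

#' Phraseness of a candidate phrase
#'
#' The pointwise Kullback-Leibler contribution
#' `P_fg(phrase) * ln(P_fg(phrase) / prod_i P_fg(word_i))`: how much more
#' likely the words are to occur together than would be expected if they
#' occurred independently, under the foreground language model. Exactly 0
#' for single words.
#'
#' @param phrase Character scalar (words separated by spaces).
#' @param fg_lm Foreground language model from [build_lm()].
#' @return Scalar phraseness (natural log).
#' @export
phraseness <- function(phrase, fg_lm) {
  words <- strsplit(phrase, " ", fixed = TRUE)[[1]]
  if (length(words) == 1) return(0)
  p_phrase <- fg_lm(phrase)
  p_words <- vapply(words, fg_lm, numeric(1))
  if (p_phrase <= 0) {
    abort(paste0("phrase has zero foreground probability: ", phrase),
          class = "endovoices_config_error")
  }
  if (any(p_words <= 0)) {
    abort(paste0("zero unigram probability inside phrase: ", phrase),
          class = "endovoices_config_error")
  }
  p_phrase * log(p_phrase / prod(p_words))
}

#' Informativeness of a candidate phrase
#'
#' The pointwise Kullback-Leibler contribution
#' `P_fg(phrase) * ln(P_fg(phrase) / P_bg(phrase))`: the expected
#' information lost when the background distribution is used to
#' approximate the foreground — large and positive for phrases much more
#' frequent in the survey responses than in ordinary language, negative
#' for phrases rarer in the foreground. The background model must be
#' smoothed so phrases unseen in the background keep a finite floor.
#'
#' @inheritParams phraseness
#' @param bg_lm Smoothed background language model.
#' @return Scalar informativeness (natural log).
#' @export
informativeness <- function(phrase, fg_lm, bg_lm) {
  p_fg <- fg_lm(phrase)
  p_bg <- bg_lm(phrase)
  if (p_fg <= 0) {
    abort(paste0("phrase has zero foreground probability: ", phrase),
          class = "endovoices_config_error")
  }
  if (p_bg <= 0) {
    abort(paste0("background model is unsmoothed for phrase: ", phrase),
          class = "endovoices_config_error")
  }
  p_fg * log(p_fg / p_bg)
}

#' Rank a group's distinctive phrases by KLIP
#'
#' The full extraction pipeline for one disease group: candidate
#' enumeration under the length/boundary/frequency constraints,
#' per-respondent de-duplication of 3-4-grams, foreground and background
#' language models, and the combined score
#' `klip = gamma * informativeness + (1 - gamma) * phraseness` with
#' gamma = 0.8 by default (informativeness-dominant). The alternative
#' orientation — gamma weighting phraseness — is available via
#' `gamma_on = "phraseness"`. Ties are broken by foreground count, then
#' lexicographically.
#'
#' The foreground model is unsmoothed maximum likelihood per phrase
#' length (candidates always have positive foreground counts); the
#' background model uses add-alpha smoothing over the union vocabulary of
#' foreground and background n-grams of each length.
#'
#' @param documents Prepared document tibble for one group.
#' @param background A `background_corpus`.
#' @param gamma Balance parameter in \[0, 1\].
#' @param gamma_on Which component gamma multiplies.
#' @param alpha Background smoothing constant.
#' @param max_len,min_count Candidate constraints.
#' @return Tibble sorted by descending KLIP: `phrase`, `length`,
#'   `fg_count`, `phraseness`, `informativeness`, `klip`.
#' @export
klip_rank <- function(documents, background, gamma = 0.8,
                      gamma_on = c("informativeness", "phraseness"),
                      alpha = 1, max_len = 4, min_count = 2) {
  gamma_on <- match.arg(gamma_on)
  if (gamma < 0 || gamma > 1) {
    config_error("'gamma' must be in [0, 1]", field = "gamma")
  }
  cand <- dedup_per_respondent(
    extract_candidates(documents, max_len = max_len, min_count = min_count),
    min_count = min_count)
  if (nrow(cand) == 0) {
    return(tibble::tibble(phrase = character(0), length = integer(0),
                          fg_count = integer(0), phraseness = numeric(0),
                          informativeness = numeric(0), klip = numeric(0)))
  }
  fg_counts <- count_ngrams(documents$tokens, max_len = max_len)
  # de-duplicated counts replace raw counts for the scored candidates
  for (i in seq_len(nrow(cand))) {
    fg_counts$counts[[cand$length[i]]][[cand$phrase[i]]] <- cand$fg_count[i]
  }
  fg_lm <- build_lm(fg_counts$counts, fg_counts$totals, alpha = 0)
  vocab_sizes <- vapply(seq_len(max_len), function(l) {
    length(union(names(fg_counts$counts[[l]]),
                 names(background$counts[[l]])))
  }, integer(1))
  bg_lm <- build_lm(background$counts, background$totals, alpha = alpha,
                    vocab_sizes = vocab_sizes)
  ph <- vapply(cand$phrase, phraseness, numeric(1), fg_lm = fg_lm)
  inf <- vapply(cand$phrase, informativeness, numeric(1), fg_lm = fg_lm,
                bg_lm = bg_lm)
  klip <- if (gamma_on == "informativeness") {
    gamma * inf + (1 - gamma) * ph
  } else {
    gamma * ph + (1 - gamma) * inf
  }
  out <- tibble::tibble(phrase = cand$phrase, length = cand$length,
                        fg_count = cand$fg_count,
                        phraseness = unname(ph),
                        informativeness = unname(inf),
                        klip = unname(klip))
  out[order(-out$klip, -out$fg_count, out$phrase), , drop = FALSE]
}

#' Per-group phrase rankings
#'
#' Runs [klip_rank()] once per MTG in the document set.
#'
#' @inheritParams klip_rank
#' @param document_set Prepared document tibble with an `mtg` column.
#' @return Named list of ranking tibbles, one per group.
#' @export
klip_by_group <- function(document_set, background, gamma = 0.8, ...) {
  groups <- split(seq_len(nrow(document_set)), document_set$mtg)
  lapply(groups, function(idx) {
    klip_rank(document_set[idx, , drop = FALSE], background,
              gamma = gamma, ...)
  })
}
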