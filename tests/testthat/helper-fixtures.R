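# Shared fixtures and independent oracles, all built in code.

# minimal wide response table; ratings passed as a named list of vectors
make_records <- function(n, ratings = list(), mtg = "Adrenal",
                         gender = "female", country = "Sweden",
                         role = "patient") {
  out <- tibble::tibble(
    respondent_id = sprintf("X%04d", seq_len(n)),
    gender = rep_len(gender, n), age_band = rep_len("41-50", n),
    country = rep_len(country, n), mtg = rep_len(mtg, n),
    is_member = rep_len(TRUE, n), role = rep_len(role, n))
  for (tp in priority_topics()) {
    out[[paste0("rating_", tp)]] <- if (tp %in% names(ratings)) {
      as.integer(ratings[[tp]])
    } else {
      rep(1L, n)
    }
  }
  out
}

# hand-built document set: token/mask lists assembled without the package
# tokeniser so candidate tests control adjacency exactly
make_docs <- function(token_lists, masks = NULL, respondent_ids = NULL,
                      mtg = "Adrenal", question_id = "q_night") {
  n <- length(token_lists)
  if (is.null(masks)) {
    sw <- stopwords_en()
    masks <- lapply(token_lists, function(tk) tk %in% sw)
  }
  if (is.null(respondent_ids)) respondent_ids <- sprintf("X%04d", seq_len(n))
  out <- tibble::tibble(
    respondent_id = respondent_ids,
    question_id = rep_len(question_id, n),
    mtg = rep_len(mtg, n),
    text = vapply(token_lists, paste, character(1), collapse = " "),
    tokens = token_lists, stopword_mask = masks)
  class(out) <- c("document_set", class(out))
  out
}

# --- independent Student-t oracle: numeric quadrature of the density ----
t_density <- function(x, df) {
  gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
    (1 + x^2 / df)^(-(df + 1) / 2)
}

p_two_sided_t_quadrature <- function(tstat, df) {
  tail <- stats::integrate(t_density, lower = abs(tstat), upper = Inf,
                           df = df, rel.tol = 1e-10)$value
  2 * tail
}

# --- brute-force KLIP oracle -------------------------------------------
# Direct enumeration of every n-gram, per-respondent de-duplication for
# 3-4-grams, and literal evaluation of both pointwise KL terms. Kept
# deliberately naive and separate from the package implementation.
brute_klip <- function(docs, bg_counts, bg_totals, gamma = 0.8, alpha = 1,
                       max_len = 4, min_count = 2) {
  # every occurrence of every n-gram, with its respondent
  occ <- list()
  for (i in seq_len(nrow(docs))) {
    tk <- docs$tokens[[i]]
    mask <- docs$stopword_mask[[i]]
    for (l in seq_len(max_len)) {
      s <- 1
      while (s + l - 1 <= length(tk)) {
        g <- paste(tk[s:(s + l - 1)], collapse = " ")
        occ[[length(occ) + 1]] <- list(
          gram = g, len = l, resp = docs$respondent_id[[i]],
          ok = !mask[s] && !mask[s + l - 1])
        s <- s + 1
      }
    }
  }
  grams <- vapply(occ, `[[`, character(1), "gram")
  lens <- vapply(occ, `[[`, integer(1), "len")
  resps <- vapply(occ, `[[`, character(1), "resp")
  oks <- vapply(occ, `[[`, logical(1), "ok")

  totals <- vapply(seq_len(max_len), function(l) sum(lens == l), integer(1))
  raw_counts <- lapply(seq_len(max_len), function(l) table(grams[lens == l]))

  cands <- unique(grams[oks])
  rows <- list()
  for (g in cands) {
    l <- length(strsplit(g, " ")[[1]])
    if (sum(grams == g) < min_count) next
    cnt <- if (l >= 3) {
      length(unique(resps[grams == g]))
    } else {
      sum(grams == g)
    }
    if (cnt < min_count) next
    p_fg <- cnt / totals[l]
    # foreground unigram probabilities for the phraseness product
    words <- strsplit(g, " ")[[1]]
    p_words <- vapply(words, function(w) {
      c_w <- sum(grams == w & lens == 1)
      c_w / totals[1]
    }, numeric(1))
    ph <- if (l == 1) 0 else p_fg * log(p_fg / prod(p_words))
    v_l <- length(unique(c(names(raw_counts[[l]]),
                           names(bg_counts[[l]]))))
    c_bg <- if (g %in% names(bg_counts[[l]])) bg_counts[[l]][[g]] else 0
    p_bg <- (c_bg + alpha) / (bg_totals[l] + alpha * v_l)
    inf <- p_fg * log(p_fg / p_bg)
    rows[[g]] <- data.frame(phrase = g, length = l, fg_count = cnt,
                            phraseness = ph, informativeness = inf,
                            klip = gamma * inf + (1 - gamma) * ph,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$klip, -out$fg_count, out$phrase), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# tiny random corpora for property tests
random_docs <- function(n_docs, vocab, n_tokens = 8, seed = 1,
                        n_resp = n_docs) {
  set.seed(seed)
  make_docs(
    lapply(seq_len(n_docs), function(i) {
      sample(vocab, sample(3:n_tokens, 1), replace = TRUE)
    }),
    respondent_ids = sprintf("X%04d", sample.int(n_resp, n_docs,
                                                 replace = TRUE)))
}

lemma_phrase <- function(p) {
  paste(tokenize_lemmatize(p)$tokens, collapse = " ")
}
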