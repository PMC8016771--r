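#' Build a TF-IDF document-term matrix
#'
#' Weight(d, t) = tf(d, t) * ln(N / df(t)) with raw term counts and an
#' unsmoothed idf, so a term present in every document gets weight exactly
#' zero — ubiquitous words cannot influence the factorisation. Stop words
#' are excluded from the vocabulary; terms with document frequency below
#' `min_df`, or with zero weight everywhere, are pruned.
#'
#' @param document_set Prepared document tibble (with `tokens` and
#'   `stopword_mask` list-columns).
#' @param min_df Minimum document frequency to keep a term.
#' @param keep_stopwords If TRUE, stop words stay in the vocabulary
#'   (mainly for diagnostics).
#' @return A `term_weight_matrix`: list with `matrix` (sparse documents x
#'   terms), `vocabulary`, `doc_ids`.
#' @export
build_tfidf <- function(document_set, min_df = 2, keep_stopwords = FALSE) {
  n_docs <- nrow(document_set)
  if (n_docs < 2) {
    config_error("TF-IDF needs at least 2 documents", field = "document_set")
  }
  toks <- lapply(seq_len(n_docs), function(i) {
    tk <- document_set$tokens[[i]]
    if (!keep_stopwords) tk <- tk[!document_set$stopword_mask[[i]]]
    tk
  })
  vocab <- sort(unique(unlist(toks)))
  if (length(vocab) == 0) {
    config_error("empty vocabulary after stop-word filtering",
                 field = "document_set")
  }
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (i in seq_len(n_docs)) {
    if (length(toks[[i]]) == 0) next
    tf <- table(toks[[i]])
    ii <- c(ii, rep(i, length(tf)))
    jj <- c(jj, match(names(tf), vocab))
    xx <- c(xx, as.numeric(tf))
  }
  tfm <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                              dims = c(n_docs, length(vocab)))
  df <- Matrix::colSums(tfm > 0)
  idf <- log(n_docs / df)
  w <- tfm %*% Matrix::Diagonal(x = idf)
  keep <- df >= min_df & idf > 0
  if (!any(keep)) {
    config_error("empty vocabulary after df filtering", field = "min_df")
  }
  w <- w[, keep, drop = FALSE]
  structure(list(matrix = methods::as(w, "CsparseMatrix"),
                 vocabulary = vocab[keep],
                 doc_ids = paste(document_set$respondent_id,
                                 document_set$question_id, sep = ":")),
            class = "term_weight_matrix")
}

#' @export
print.term_weight_matrix <- function(x, ...) {
  cat(sprintf("TF-IDF term-weight matrix: %d documents x %d terms\n",
              nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

# NNDSVD: deterministic SVD-based non-negative initialisation
# (Boutsidis & Gallopoulos); zero entries filled with a small
# seed-dependent jitter so the multiplicative updates can move them
nndsvd_init <- function(V, k, seed) {
  V <- as.matrix(V)
  s <- svd(V, nu = k, nv = k)
  W <- matrix(0, nrow(V), k)
  H <- matrix(0, k, ncol(V))
  W[, 1] <- sqrt(s$d[1]) * abs(s$u[, 1])
  H[1, ] <- sqrt(s$d[1]) * abs(s$v[, 1])
  if (k > 1) {
    for (j in 2:k) {
      u <- s$u[, j]; v <- s$v[, j]
      up <- pmax(u, 0); un <- pmax(-u, 0)
      vp <- pmax(v, 0); vn <- pmax(-v, 0)
      np <- sqrt(sum(up^2)) * sqrt(sum(vp^2))
      nn <- sqrt(sum(un^2)) * sqrt(sum(vn^2))
      if (np >= nn && np > 0) {
        W[, j] <- sqrt(s$d[j] * np) * up / sqrt(sum(up^2))
        H[j, ] <- sqrt(s$d[j] * np) * vp / sqrt(sum(vp^2))
      } else if (nn > 0) {
        W[, j] <- sqrt(s$d[j] * nn) * un / sqrt(sum(un^2))
        H[j, ] <- sqrt(s$d[j] * nn) * vn / sqrt(sum(vn^2))
      }
    }
  }
  eps <- mean(V) * 1e-4
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(seed, "nndsvd"))
  W[W <= 0] <- eps * runif(sum(W <= 0))
  H[H <= 0] <- eps * runif(sum(H <= 0))
  list(W = W, H = H)
}

#' Fit a non-negative matrix factorisation
#'
#' Factorises the non-negative TF-IDF matrix V (documents x terms) into
#' W (documents x k) and H (k x terms), both non-negative, by
#' multiplicative Frobenius updates from a deterministic SVD-based
#' initialisation. The reconstruction error ||V - WH||_F is
#' non-increasing across iterations; iteration stops at `max_iter` or
#' when the relative error improvement falls below `tol`. Identical
#' matrix, k and seed give identical factors. Topics are read off as the
#' highest-weight terms per row of H.
#'
#' @param x A `term_weight_matrix` from [build_tfidf()].
#' @param k Number of topics, 1 <= k <= min(dim(V)).
#' @param seed Integer seed (used only to fill zero entries of the
#'   deterministic initialisation).
#' @param max_iter,tol Stopping rule.
#' @param n_top_words Number of top words reported per topic.
#' @return A `topic_model`: k, W, H, `top_words` (list of character
#'   vectors), `reconstruction_error`, `error_trace`, `seed`.
#' @export
fit_nmf <- function(x, k, seed = 1L, max_iter = 500, tol = 1e-5,
                    n_top_words = 10) {
  stopifnot(inherits(x, "term_weight_matrix"))
  V <- as.matrix(x$matrix)
  if (k < 1 || k > min(dim(V))) {
    config_error(sprintf("k = %d outside valid range 1..%d", k, min(dim(V))),
                 field = "k")
  }
  init <- nndsvd_init(V, k, seed)
  W <- init$W; H <- init$H
  eps <- .Machine$double.eps
  err <- sqrt(sum((V - W %*% H)^2))
  trace <- err
  for (it in seq_len(max_iter)) {
    H <- H * (crossprod(W, V)) / (crossprod(W, W %*% H) + eps)
    W <- W * (V %*% t(H)) / (W %*% tcrossprod(H, H) + eps)
    if (it %% 10 == 0 || it == max_iter) {
      new_err <- sqrt(sum((V - W %*% H)^2))
      trace <- c(trace, new_err)
      if ((err - new_err) < tol * err) {
        err <- new_err
        break
      }
      err <- new_err
    }
  }
  top <- lapply(seq_len(k), function(j) {
    x$vocabulary[order(H[j, ], decreasing = TRUE)[
      seq_len(min(n_top_words, ncol(V)))]]
  })
  structure(list(k = k, W = W, H = H, vocabulary = x$vocabulary,
                 doc_ids = x$doc_ids, top_words = top,
                 reconstruction_error = err, error_trace = trace,
                 seed = seed),
            class = "topic_model")
}

#' @export
print.topic_model <- function(x, ...) {
  cat(sprintf("NMF topic model: k = %d, reconstruction error %.4f\n",
              x$k, x$reconstruction_error))
  for (j in seq_len(x$k)) {
    cat(sprintf("  topic %d: %s\n", j,
                paste(head(x$top_words[[j]], 10), collapse = ", ")))
  }
  invisible(x)
}

#' Train word embeddings on the analysis corpus
#'
#' Skip-gram embeddings with negative sampling, trained by SGD on the
#' survey corpus itself so that words used in similar contexts get
#' similar vectors. Training is single-threaded with a self-contained
#' RNG: a fixed seed gives bit-identical vectors. `min_count = 1` by
#' default so every term of the TF-IDF vocabulary has a vector.
#'
#' @param document_set Prepared document tibble.
#' @param dim Vector dimension.
#' @param window Maximum context window (sampled uniformly per position).
#' @param min_count Minimum corpus frequency for a word to be embedded.
#' @param epochs Training epochs.
#' @param negative Negative samples per positive pair.
#' @param alpha Initial learning rate (linear decay).
#' @param seed Integer seed.
#' @return An `embedding_map`: numeric matrix, one row per word.
#' @export
train_embeddings <- function(document_set, dim = 100, window = 5,
                             min_count = 1, epochs = 50, negative = 5,
                             alpha = 0.025, seed = 1L) {
  toks <- document_set$tokens
  if (length(toks) == 0 || sum(lengths(toks)) == 0) {
    config_error("corpus is empty", field = "document_set")
  }
  cnt <- table(unlist(toks))
  vocab <- sort(names(cnt[cnt >= min_count]))
  counts <- as.numeric(cnt[vocab])
  stream <- unlist(lapply(toks, function(tk) {
    c(match(tk, vocab) - 1L, -1L)  # -1 separates documents
  }))
  stream[is.na(stream)] <- -1L
  mat <- skipgram_train_cpp(as.integer(stream), length(vocab), counts,
                            as.integer(dim), as.integer(window),
                            as.integer(negative), as.integer(epochs),
                            alpha, as.integer(seed))
  rownames(mat) <- vocab
  structure(mat, class = c("embedding_map", class(mat)),
            params = list(dim = dim, window = window, min_count = min_count,
                          epochs = epochs, negative = negative,
                          alpha = alpha, seed = seed))
}

#' @export
print.embedding_map <- function(x, ...) {
  cat(sprintf("word embeddings: %d words x %d dimensions\n",
              nrow(x), ncol(x)))
  invisible(x)
}

cosine_sim <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

#' TC-W2V coherence of one topic
#'
#' Mean cosine similarity, under the word embeddings, over all unordered
#' pairs of the topic's top words; bounded in \[-1, 1\] and invariant
#' under permutation of the word list. Higher = the topic's words live
#' closer together in embedding space = a more humanly coherent topic.
#'
#' @param top_words Character vector (>= 2 words).
#' @param embeddings An `embedding_map`.
#' @return Scalar coherence.
#' @export
tcw2v_coherence <- function(top_words, embeddings) {
  stopifnot(length(top_words) >= 2)
  missing_terms <- setdiff(top_words, rownames(embeddings))
  if (length(missing_terms) > 0) {
    abort(paste0("no embedding vector for term(s): ",
                 paste(missing_terms, collapse = ", ")),
          class = "endovoices_config_error")
  }
  pairs <- combn(top_words, 2)
  mean(vapply(seq_len(ncol(pairs)), function(j) {
    cosine_sim(embeddings[pairs[1, j], ], embeddings[pairs[2, j], ])
  }, numeric(1)))
}

#' Select the number of topics by mean TC-W2V coherence
#'
#' Fits one NMF per candidate k and scores each model by the arithmetic
#' mean of its per-topic coherences; the selected k maximises the mean
#' coherence, with ties broken toward the smaller k (and flagged). All
#' per-k models are returned for audit.
#'
#' @param x A `term_weight_matrix`.
#' @param k_range Candidate numbers of topics (default 2:15).
#' @param embeddings An `embedding_map` covering the vocabulary.
#' @param seed Seed passed to each NMF fit.
#' @param n_top_words Top words per topic used for coherence.
#' @return A `k_selection`: `k_star`, `tie`, `coherence` tibble
#'   (k, mean_coherence), `models` (list of `topic_model`s, named by k).
#' @export
select_k <- function(x, k_range = 2:15, embeddings, seed = 1L,
                     n_top_words = 10) {
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 1) || any(k_range > min(dim(x$matrix)))) {
    config_error("k_range outside valid bounds", field = "k_range")
  }
  models <- list()
  rows <- list()
  for (k in k_range) {
    fit <- tryCatch(
      fit_nmf(x, k, seed = seed, n_top_words = n_top_words),
      error = function(e) e)
    if (inherits(fit, "error")) next
    coh <- vapply(fit$top_words, tcw2v_coherence, numeric(1),
                  embeddings = embeddings)
    fit$coherence_per_topic <- coh
    fit$mean_coherence <- mean(coh)
    models[[as.character(k)]] <- fit
    rows[[as.character(k)]] <- tibble::tibble(k = k, mean_coherence = mean(coh))
  }
  if (length(models) == 0) {
    abort("no NMF fit succeeded over k_range",
          class = "endovoices_config_error")
  }
  coh_tbl <- dplyr::bind_rows(rows)
  best <- max(coh_tbl$mean_coherence)
  at_best <- coh_tbl$k[coh_tbl$mean_coherence == best]
  structure(list(k_star = min(at_best), tie = length(at_best) > 1,
                 coherence = coh_tbl, models = models),
            class = "k_selection")
}

#' @export
print.k_selection <- function(x, ...) {
  cat(sprintf("selected k = %d%s\n", x$k_star,
              if (x$tie) " (tie, smallest k chosen)" else ""))
  print(as.data.frame(x$coherence), row.names = FALSE)
  invisible(x)
}
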