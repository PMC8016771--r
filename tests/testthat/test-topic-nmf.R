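test_that("TF-IDF closed forms: ubiquitous terms vanish, singleton terms weigh tf*ln(N/df)", {
  docs <- make_docs(list(
    c("adrenal", "adrenal", "adrenal", "tired"),
    c("tired", "sleep")))
  tw <- build_tfidf(docs, min_df = 1)
  # "tired" occurs in both documents: idf = ln(1) = 0, pruned
  expect_false("tired" %in% tw$vocabulary)
  # "adrenal" in one of two docs with tf 3: weight 3 * ln 2
  expect_equal(tw$matrix[1, match("adrenal", tw$vocabulary)], 3 * log(2),
               tolerance = 1e-12)
})

test_that("TF-IDF matches a hand-computed table on a 4-document corpus", {
  docs <- make_docs(list(
    c("pain", "pain", "sleep"),
    c("pain", "fatigue"),
    c("sleep", "fatigue", "fatigue", "hope"),
    c("hope", "pain")))
  tw <- build_tfidf(docs, min_df = 1)
  v <- tw$vocabulary
  m <- as.matrix(tw$matrix)
  # document frequencies: pain 3, sleep 2, fatigue 2, hope 2
  expect_equal(m[1, match("pain", v)], 2 * log(4 / 3), tolerance = 1e-12)
  expect_equal(m[2, match("pain", v)], 1 * log(4 / 3), tolerance = 1e-12)
  expect_equal(m[1, match("sleep", v)], 1 * log(2), tolerance = 1e-12)
  expect_equal(m[3, match("fatigue", v)], 2 * log(2), tolerance = 1e-12)
  expect_equal(m[3, match("hope", v)], 1 * log(2), tolerance = 1e-12)
  expect_equal(m[4, match("hope", v)], 1 * log(2), tolerance = 1e-12)
  expect_equal(m[2, match("sleep", v)], 0)
  # stop words never enter the vocabulary
  docs2 <- make_docs(list(c("the", "pain", "pain"), c("pain", "the", "sleep")))
  tw2 <- build_tfidf(docs2, min_df = 1)
  expect_false("the" %in% tw2$vocabulary)
})

test_that("TF-IDF respects min_df and document reordering permutes rows only", {
  docs <- make_docs(list(c("aa", "bb"), c("aa", "cc"), c("bb", "dd")))
  tw <- build_tfidf(docs, min_df = 2)
  expect_setequal(tw$vocabulary, c("aa", "bb"))
  perm <- docs[c(3, 1, 2), ]
  tw_perm <- build_tfidf(perm, min_df = 2)
  expect_equal(as.matrix(tw_perm$matrix),
               as.matrix(tw$matrix)[c(3, 1, 2), , drop = FALSE])
  expect_error(build_tfidf(make_docs(list(c("the"), c("a"))), min_df = 1),
               class = "endovoices_config_error")
})

test_that("NMF reconstructs an exact rank-1 matrix and is deterministic", {
  w <- c(1, 2, 3, 4); h <- c(2, 0.5, 1)
  V <- outer(w, h)
  tw <- structure(list(matrix = V, vocabulary = c("t1", "t2", "t3"),
                       doc_ids = paste0("d", 1:4)),
                  class = "term_weight_matrix")
  fit <- fit_nmf(tw, 1, seed = 5)
  expect_lt(fit$reconstruction_error, 1e-6)
  expect_true(all(fit$W >= 0) && all(fit$H >= 0))

  fit2 <- fit_nmf(tw, 1, seed = 5)
  expect_identical(fit$W, fit2$W)
  expect_identical(fit$H, fit2$H)
  expect_error(fit_nmf(tw, 4, seed = 1), class = "endovoices_config_error")
})

test_that("NMF separates a block-diagonal two-topic matrix", {
  set.seed(77)
  blockA <- matrix(runif(5 * 4, 1, 2), 5, 4)
  blockB <- matrix(runif(5 * 4, 1, 2), 5, 4)
  V <- rbind(cbind(blockA, matrix(0, 5, 4)),
             cbind(matrix(0, 5, 4), blockB))
  vocab <- c(paste0("a", 1:4), paste0("b", 1:4))
  tw <- structure(list(matrix = V, vocabulary = vocab,
                       doc_ids = paste0("d", 1:10)),
                  class = "term_weight_matrix")
  fit <- fit_nmf(tw, 2, seed = 3, n_top_words = 4)
  tops <- lapply(fit$top_words, function(w) unique(substr(w, 1, 1)))
  expect_setequal(unlist(lapply(tops, `[[`, 1)), c("a", "b"))
  expect_true(all(lengths(tops) == 1))
})

test_that("NMF error trace is non-increasing", {
  docs <- random_docs(30, c(paste0("w", 1:15)), seed = 4)
  tw <- build_tfidf(docs, min_df = 1)
  fit <- fit_nmf(tw, 3, seed = 4)
  expect_true(all(diff(fit$error_trace) <= 1e-8))
})

test_that("embeddings are deterministic per seed, differ across seeds, cover the vocabulary", {
  coh <- generate_cohort(cohort_spec(n_respondents = 30, seed = 15))
  docs <- prepare_documents(generate_open_text(text_spec(seed = 15), coh))
  e1 <- train_embeddings(docs, dim = 20, epochs = 3, seed = 1)
  e2 <- train_embeddings(docs, dim = 20, epochs = 3, seed = 1)
  expect_identical(unclass(e1)[, ], unclass(e2)[, ])
  e3 <- train_embeddings(docs, dim = 20, epochs = 3, seed = 2)
  expect_false(rlang::hash(unclass(e1)[, ]) == rlang::hash(unclass(e3)[, ]))

  tw <- build_tfidf(docs)
  expect_true(all(tw$vocabulary %in% rownames(e1)))
  # self-similarity is exactly 1
  v <- e1["tired", ]
  expect_equal(sum(v * v) / (sqrt(sum(v^2)) * sqrt(sum(v^2))), 1,
               tolerance = 1e-12)
})

test_that("tokens sharing contexts end up with similar vectors", {
  # distributionally interchangeable tokens: each document carries either
  # "aa" or "bb" in the same slot, surrounded by the same context pool
  set.seed(10)
  ctx <- paste0("c", 1:12)
  token_lists <- lapply(1:200, function(i) {
    c(sample(ctx, 3, replace = TRUE), sample(c("aa", "bb"), 1),
      sample(ctx, 3, replace = TRUE))
  })
  docs <- make_docs(token_lists, masks = lapply(token_lists,
                                                function(x) rep(FALSE, 7)))
  emb <- train_embeddings(docs, dim = 30, window = 3, epochs = 60, seed = 4)
  sim_ab <- sum(emb["aa", ] * emb["bb", ]) /
    (sqrt(sum(emb["aa", ]^2)) * sqrt(sum(emb["bb", ]^2)))
  expect_gt(sim_ab, 0.8)
})

test_that("TC-W2V coherence is the mean pairwise cosine, bounded and permutation invariant", {
  emb <- rbind(w1 = c(1, 0, 0), w2 = c(1, 0, 0), w3 = c(0, 1, 0),
               w4 = c(1, 1, 0))
  class(emb) <- c("embedding_map", class(emb))
  expect_equal(tcw2v_coherence(c("w1", "w2"), emb), 1)
  expect_equal(tcw2v_coherence(c("w1", "w3"), emb), 0)
  # hand-computed mean of the 6 pairwise cosines
  s <- sqrt(2) / 2
  hand <- mean(c(1, 0, s, 0, s, s))
  expect_equal(tcw2v_coherence(c("w1", "w2", "w3", "w4"), emb), hand,
               tolerance = 1e-12)
  expect_equal(tcw2v_coherence(c("w4", "w3", "w2", "w1"), emb), hand,
               tolerance = 1e-12)
  expect_gte(hand, -1); expect_lte(hand, 1)
  expect_error(tcw2v_coherence(c("w1", "nope"), emb),
               class = "endovoices_config_error")
})

test_that("select_k maximises mean coherence with ties to the smaller k", {
  docs <- random_docs(40, paste0("w", 1:12), seed = 9)
  tw <- build_tfidf(docs, min_df = 1)
  # identical vectors for every term force a coherence tie at 1
  emb <- matrix(1, nrow = length(tw$vocabulary), ncol = 4,
                dimnames = list(tw$vocabulary, NULL))
  class(emb) <- c("embedding_map", class(emb))
  sel <- select_k(tw, 2:4, emb, seed = 1, n_top_words = 3)
  expect_equal(sel$k_star, 2)
  expect_true(sel$tie)
  expect_equal(nrow(sel$coherence), 3)

  sel1 <- select_k(tw, 2, emb, seed = 1, n_top_words = 3)
  expect_equal(sel1$k_star, 2)
  expect_false(sel1$tie)
})
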