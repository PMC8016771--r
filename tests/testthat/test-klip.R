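test_that("candidate phrases never start or end with a stop word", {
  docs <- make_docs(list(c("the", "adrenal", "crisis"),
                         c("the", "adrenal", "crisis")),
                    masks = list(c(TRUE, FALSE, FALSE),
                                 c(TRUE, FALSE, FALSE)))
  cand <- extract_candidates(docs)
  expect_setequal(cand$phrase, c("adrenal", "crisis", "adrenal crisis"))
  expect_false("the adrenal" %in% cand$phrase)
  expect_false("the adrenal crisis" %in% cand$phrase)
})

test_that("phrases occurring once are excluded; interior stop words allowed", {
  docs <- make_docs(list(c("quality", "of", "life", "matters"),
                         c("quality", "of", "life", "always")),
                    masks = list(c(FALSE, TRUE, FALSE, FALSE),
                                 c(FALSE, TRUE, FALSE, FALSE)))
  cand <- extract_candidates(docs)
  expect_true("quality of life" %in% cand$phrase)  # interior stop word
  expect_false("matters" %in% cand$phrase)         # single occurrence
  expect_true(all(cand$fg_count >= 2))
})

test_that("candidates never span across responses", {
  # both responses end/start with the same words; the would-be
  # cross-boundary bigram "release slow" must not appear
  docs <- make_docs(list(c("slow", "release"), c("slow", "release")))
  cand <- extract_candidates(docs)
  expect_true("slow release" %in% cand$phrase)
  expect_false("release slow" %in% cand$phrase)
})

test_that("per-respondent de-duplication collapses 3-4-grams only", {
  tk <- c("slow", "release", "thyroid", "drug")
  docs <- make_docs(list(tk, tk, tk, tk),
                    respondent_ids = c("p1", "p1", "p1", "p2"))
  cand <- extract_candidates(docs)
  dd <- dedup_per_respondent(cand)
  four <- dd[dd$phrase == "slow release thyroid drug", ]
  expect_equal(four$fg_count, 2)  # 3 by p1 collapse to 1, +1 by p2
  tri <- dd[dd$phrase == "slow release thyroid", ]
  expect_equal(tri$fg_count, 2)
  bi <- dd[dd$phrase == "slow release", ]
  expect_equal(bi$fg_count, 4)    # bigrams untouched
  uni <- dd[dd$phrase == "thyroid", ]
  expect_equal(uni$fg_count, 4)
  # no repeats -> identity
  docs2 <- make_docs(list(c("slow", "release", "thyroid")),
                     respondent_ids = "p1")
  cand2 <- extract_candidates(docs2, min_count = 1)
  expect_equal(dedup_per_respondent(cand2, min_count = 1), cand2)
})

test_that("add-alpha language models follow the closed form", {
  counts <- list(setNames(c(3L, 1L), c("pain", "sleep")),
                 setNames(2L, "chronic pain"))
  totals <- c(4L, 3L)
  ml <- build_lm(counts, totals, alpha = 0)
  expect_equal(ml("pain"), 3 / 4)
  expect_equal(ml("chronic pain"), 2 / 3)
  expect_equal(ml("absent"), 0)
  lap <- build_lm(counts, totals, alpha = 1, vocab_sizes = c(10L, 20L))
  expect_equal(lap("absent"), 1 / (4 + 10))
  expect_equal(lap("never seen"), 1 / (3 + 20))
  # unsmoothed probabilities over the seen set form a sub-distribution
  expect_lte(ml("pain") + ml("sleep"), 1)
})

test_that("phraseness is zero for single words and positive for bound pairs", {
  # 10-token toy corpus where "slow" and "release" only occur together
  docs <- make_docs(list(c("slow", "release", "drug", "form"),
                         c("slow", "release", "dose", "form"),
                         c("drug", "dose")))
  fgc <- list(
    setNames(c(2L, 2L, 2L, 2L, 2L), c("slow", "release", "drug", "form", "dose")),
    setNames(c(2L), "slow release"))
  fg <- build_lm(fgc, c(10L, 7L), alpha = 0)
  expect_equal(phraseness("slow", fg), 0)
  p <- fg("slow release")
  hand <- p * log(p / (fg("slow") * fg("release")))
  expect_equal(phraseness("slow release", fg), hand, tolerance = 1e-12)
  expect_gt(hand, 0)
})

test_that("phraseness vanishes for independent words", {
  # counts constructed so P(xy) = P(x) * P(y) exactly
  fgc <- list(setNames(c(10L, 10L), c("x", "y")),
              setNames(4L, "x y"))
  fg <- build_lm(fgc, c(20L, 16L), alpha = 0)
  # P(x y) = 4/16 = 0.25 = (10/20) * (10/20)
  expect_equal(phraseness("x y", fg), 0, tolerance = 1e-12)
})

test_that("informativeness has the sign of the frequency log-ratio", {
  fg <- build_lm(list(setNames(c(5L, 1L, 2L), c("a", "b", "c"))), 8L,
                 alpha = 0)
  bg <- build_lm(list(setNames(c(5L, 4L, 16L), c("a", "b", "c"))), 25L,
                 alpha = 1, vocab_sizes = 5L)
  # equal probabilities -> 0: P_fg(a) = 5/8; choose bg giving the same
  bg_eq <- build_lm(list(setNames(5L, "a")), 8L, alpha = 0)
  expect_equal(informativeness("a", fg, bg_eq), 0, tolerance = 1e-12)
  # more frequent in foreground than background -> positive
  expect_gt(informativeness("a", fg, bg), 0)
  # rarer in foreground than background -> negative
  expect_lt(informativeness("c", fg, bg), 0)
  p_fg <- fg("b")
  floor <- 1 / (25 + 5)
  bg_unseen <- build_lm(list(setNames(5L, "zz")), 25L, alpha = 1,
                        vocab_sizes = 5L)
  expect_equal(informativeness("b", fg, bg_unseen),
               p_fg * log(p_fg / floor), tolerance = 1e-12)
})

test_that("gamma limit cases rank by a single component and klip is linear in gamma", {
  coh <- generate_cohort(cohort_spec(n_respondents = 40, seed = 18))
  planted <- tibble::tibble(mtg = "Adrenal", phrase = "slow release",
                            prob = 0.8)
  docs <- prepare_documents(
    generate_open_text(text_spec(seed = 18, planted_phrases = planted), coh))
  adr <- docs[docs$mtg == "Adrenal", ]
  bg <- background_corpus(generate_background_corpus(text_spec(seed = 18),
                                                     5000))
  r_info <- klip_rank(adr, bg, gamma = 1)
  expect_equal(r_info$klip, r_info$informativeness, tolerance = 1e-12)
  r_ph <- klip_rank(adr, bg, gamma = 0)
  expect_equal(r_ph$klip, r_ph$phraseness, tolerance = 1e-12)
  rs <- lapply(c(0, 0.25, 0.5, 0.8, 1), function(g) {
    r <- klip_rank(adr, bg, gamma = g)
    r[order(r$phrase), ]
  })
  for (i in seq_along(rs)) {
    g <- c(0, 0.25, 0.5, 0.8, 1)[i]
    expect_equal(rs[[i]]$klip,
                 g * rs[[i]]$informativeness + (1 - g) * rs[[i]]$phraseness,
                 tolerance = 1e-12)
    expect_equal(rs[[i]]$phrase, rs[[1]]$phrase)
  }
  # the alternative orientation weights phraseness by gamma
  r_alt <- klip_rank(adr, bg, gamma = 1, gamma_on = "phraseness")
  expect_equal(r_alt$klip, r_alt$phraseness, tolerance = 1e-12)
})

test_that("klip_rank agrees with the brute-force oracle on small corpora", {
  vocab <- c("pain", "sleep", "chronic", "fatigue", "the", "of", "dose")
  for (s in 1:6) {
    docs <- random_docs(6, vocab, n_tokens = 10, seed = s, n_resp = 4)
    stopifnot(sum(lengths(docs$tokens)) <= 100)
    bg_lines <- paste(c("pain of the city", "sleep comes at night",
                        "the dose makes the poison"), collapse = " ")
    bg <- background_corpus(c(bg_lines, "roads and rivers of the north"))
    got <- klip_rank(docs, bg, gamma = 0.8)
    want <- brute_klip(docs, bg$counts, bg$totals, gamma = 0.8)
    expect_equal(got$phrase, want$phrase)
    expect_equal(got$fg_count, want$fg_count)
    expect_equal(got$phraseness, want$phraseness, tolerance = 1e-12)
    expect_equal(got$informativeness, want$informativeness,
                 tolerance = 1e-12)
    expect_equal(got$klip, want$klip, tolerance = 1e-12)
  }
})

test_that("emitted candidates always satisfy the candidate invariants", {
  sw <- stopwords_en()
  vocab <- c("pain", "sleep", "chronic", "the", "of", "and", "dose", "night")
  for (s in 1:8) {
    docs <- random_docs(10, vocab, n_tokens = 9, seed = 100 + s, n_resp = 5)
    cand <- dedup_per_respondent(extract_candidates(docs))
    if (nrow(cand) == 0) next
    expect_true(all(cand$length >= 1 & cand$length <= 4))
    expect_true(all(cand$fg_count >= 2))
    words <- strsplit(cand$phrase, " ", fixed = TRUE)
    expect_false(any(vapply(words, function(w) {
      w[1] %in% sw || w[length(w)] %in% sw
    }, logical(1))))
  }
})

test_that("scaling all foreground counts leaves unsmoothed scores unchanged", {
  counts <- list(setNames(c(6L, 2L), c("a", "b")), setNames(2L, "a b"))
  lm1 <- build_lm(counts, c(8L, 6L), alpha = 0)
  counts10 <- lapply(counts, function(x) x * 10L)
  lm10 <- build_lm(counts10, c(80L, 60L), alpha = 0)
  expect_equal(phraseness("a b", lm1), phraseness("a b", lm10),
               tolerance = 1e-12)
  bg <- build_lm(list(setNames(3L, "a"), setNames(1L, "a b")), c(10L, 8L),
                 alpha = 1, vocab_sizes = c(4L, 6L))
  expect_equal(informativeness("a b", lm1, bg),
               informativeness("a b", lm10, bg), tolerance = 1e-12)
})

test_that("matched foreground and background distributions give near-zero informativeness", {
  lines <- c("pain sleep dose pain", "sleep pain dose dose")
  docs <- make_docs(lapply(lines, function(x) strsplit(x, " ")[[1]]))
  bg <- background_corpus(rep(lines, 50))
  r <- klip_rank(docs, bg, gamma = 1)
  expect_true(all(abs(r$informativeness) < 0.05))
})
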