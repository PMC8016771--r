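#' Specification of a synthetic survey cohort
#'
#' Defines the statistical structure of a simulated cohort: marginal
#' distributions of the demographic variables, per-topic baseline mean
#' priority scores on the 1-3 scale, additive (MTG, topic) mean shifts,
#' the latent rating noise, and a completely-at-random missingness rate.
#' Ratings are generated by drawing a Gaussian with mean
#' `baseline + effect` and sd `rating_noise_sd`, rounding to the nearest
#' integer and clamping into \{1, 2, 3\} — the simplest mechanism producing
#' a 3-point scale with controllable group separation.
#'
#' Defaults mirror the demographic composition and topic means reported for
#' the published cohort of 1378 respondents. The nine ratings are generated
#' independently per respondent; respondent-level correlation between
#' topics is not modelled (no such structure is reported for the real
#' cohort) but can be emulated via `rating_effects`.
#'
#' @param n_respondents Number of respondents (may be 0).
#' @param group_weights Named probabilities over [mtg_labels()].
#' @param gender_weights Named probabilities over [gender_labels()].
#' @param region_weights Named probabilities over [region_labels()].
#' @param role_weights Named probabilities over [role_labels()].
#' @param age_weights Named probabilities over [age_bands()].
#' @param member_rate Probability of advocacy-group membership.
#' @param baseline_means Named numeric, topic -> mean in \[1, 3\].
#' @param rating_effects Tibble/data.frame with columns `mtg`, `topic`,
#'   `effect` (additive shift on the latent mean), or NULL.
#' @param rating_noise_sd Positive sd of the latent Gaussian.
#' @param missing_rate Probability in \[0, 1) that a rating is absent.
#' @param seed Integer master seed.
#' @return A validated `cohort_spec` object.
#' @export
cohort_spec <- function(n_respondents,
                        group_weights = default_group_weights(),
                        gender_weights = c(female = 0.787, male = 0.206,
                                           undisclosed = 0.007),
                        region_weights = c("Eastern Europe" = 0.019,
                                           "Northern Europe" = 0.471,
                                           "Southern Europe" = 0.106,
                                           "Western Europe" = 0.389,
                                           "Non-Europe" = 0.015),
                        role_weights = c(patient = 0.885, caregiver = 0.115),
                        age_weights = default_age_weights(),
                        member_rate = 0.685,
                        baseline_means = default_baseline_means(),
                        rating_effects = NULL,
                        rating_noise_sd = 0.6,
                        missing_rate = 0.02,
                        seed = 1L) {
  if (!is.numeric(n_respondents) || length(n_respondents) != 1 ||
      n_respondents < 0 || n_respondents != floor(n_respondents)) {
    config_error("'n_respondents' must be a non-negative integer",
                 field = "n_respondents")
  }
  check_prob_map(group_weights, "group_weights")
  check_prob_map(gender_weights, "gender_weights")
  check_prob_map(region_weights, "region_weights")
  check_prob_map(role_weights, "role_weights")
  check_prob_map(age_weights, "age_weights")
  if (rating_noise_sd < 0) {
    config_error("'rating_noise_sd' must be >= 0", field = "rating_noise_sd")
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    config_error("'missing_rate' must be in [0, 1)", field = "missing_rate")
  }
  if (any(!names(baseline_means) %in% priority_topics()) ||
      any(baseline_means < 1) || any(baseline_means > 3)) {
    config_error("'baseline_means' must map priority topics into [1, 3]",
                 field = "baseline_means")
  }
  if (!is.null(rating_effects)) {
    rating_effects <- tibble::as_tibble(rating_effects)
    stopifnot(all(c("mtg", "topic", "effect") %in% names(rating_effects)))
    bad <- setdiff(rating_effects$topic, priority_topics())
    if (length(bad) > 0) {
      config_error(paste0("unknown topic in rating_effects: ",
                          paste(bad, collapse = ", ")),
                   field = "rating_effects")
    }
  }
  structure(list(
    n_respondents = as.integer(n_respondents),
    group_weights = group_weights, gender_weights = gender_weights,
    region_weights = region_weights, role_weights = role_weights,
    age_weights = age_weights, member_rate = member_rate,
    baseline_means = baseline_means, rating_effects = rating_effects,
    rating_noise_sd = rating_noise_sd, missing_rate = missing_rate,
    seed = as.integer(seed)), class = "cohort_spec")
}

#' @rdname cohort_spec
#' @export
default_group_weights <- function() {
  w <- c(539, 46, 22, 75, 48, 398, 70, 180)
  setNames(w / sum(w), mtg_labels())
}

#' @rdname cohort_spec
#' @export
default_age_weights <- function() {
  w <- c(20, 22, 110, 231, 388, 346, 198, 63)
  setNames(w / sum(w), age_bands())
}

#' @rdname cohort_spec
#' @export
default_baseline_means <- function() {
  c(heritability = 1.55, fertility = 1.73, tiredness = 1.30, sports = 1.75,
    work = 1.27, social_life = 1.26, medicine_intake = 1.36,
    sleep_quality = 1.33, physical_discomfort = 1.27)
}

# countries drawn uniformly within the sampled region
.region_countries <- list(
  "Eastern Europe" = c("Poland", "Czechia", "Hungary", "Romania"),
  "Northern Europe" = c("Sweden", "Denmark", "Norway", "United Kingdom",
                        "Finland", "Ireland"),
  "Southern Europe" = c("Italy", "Spain", "Greece", "Portugal"),
  "Western Europe" = c("Germany", "Netherlands", "France", "Belgium",
                       "Austria"),
  "Non-Europe" = c("United States", "Canada", "Australia", "Japan"))

sample_labels <- function(n, weights) {
  sample(names(weights), n, replace = TRUE, prob = weights)
}

#' Generate a synthetic cohort of survey responses
#'
#' Fully reproducible from the spec's seed; the cohort, open-text and
#' background generators each use an independent random stream derived
#' from the master seed, so adding one never perturbs another.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with one respondent per row: demographics plus nine
#'   `rating_*` columns (integer in 1..3, `NA` where missing).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_respondents
  topics <- priority_topics()
  if (n == 0) {
    empty <- tibble::tibble(
      respondent_id = character(0), gender = character(0),
      age_band = character(0), country = character(0), mtg = character(0),
      is_member = logical(0), role = character(0))
    for (tp in topics) empty[[rating_col(tp)]] <- integer(0)
    return(empty)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(spec$seed, "cohort"))

  region <- sample_labels(n, spec$region_weights)
  country <- vapply(region, function(r) {
    cs <- .region_countries[[r]]
    cs[sample.int(length(cs), 1)]
  }, character(1), USE.NAMES = FALSE)
  out <- tibble::tibble(
    respondent_id = sprintf("R%05d", seq_len(n)),
    gender = sample_labels(n, spec$gender_weights),
    age_band = sample_labels(n, spec$age_weights),
    country = country,
    mtg = sample_labels(n, spec$group_weights),
    is_member = runif(n) < spec$member_rate,
    role = sample_labels(n, spec$role_weights))

  eff <- spec$rating_effects
  for (tp in topics) {
    mu <- rep(spec$baseline_means[[tp]], n)
    if (!is.null(eff)) {
      e <- eff[eff$topic == tp, , drop = FALSE]
      if (nrow(e) > 0) {
        shift <- setNames(e$effect, e$mtg)[out$mtg]
        shift[is.na(shift)] <- 0
        mu <- mu + shift
      }
    }
    latent <- rnorm(n, mean = mu, sd = spec$rating_noise_sd)
    r <- pmin(3L, pmax(1L, as.integer(round(latent))))
    if (spec$missing_rate > 0) {
      r[runif(n) < spec$missing_rate] <- NA_integer_
    }
    out[[rating_col(tp)]] <- r
  }
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Specification of synthetic open-text responses
#'
#' Open-text answers are generated from planted per-topic word
#' distributions (each respondent writes from one latent topic), with
#' group-specific multi-word phrases inserted verbatim with a stated
#' probability — giving downstream topic-number selection and
#' distinctive-phrase extraction a known ground truth to recover.
#'
#' @param k_true Number of planted topics.
#' @param topic_word_dists List of `k_true` named probability vectors over
#'   words (each sums to 1).
#' @param doc_length_range Integer pair, inclusive bounds on document
#'   length in tokens.
#' @param planted_phrases Tibble with columns `mtg`, `phrase` (2-4 words),
#'   `prob` (per-document insertion probability), or NULL.
#' @param background_vocab_dist Named probability vector over words for the
#'   background corpus.
#' @param question_ids Ids of the open questions each respondent answers.
#' @param seed Integer master seed.
#' @return A validated `text_spec` object.
#' @export
text_spec <- function(k_true = 3,
                      topic_word_dists = default_topic_word_dists(k_true),
                      doc_length_range = c(15L, 35L),
                      planted_phrases = NULL,
                      background_vocab_dist = default_background_dist(),
                      question_ids = c("q_night", "q_research"),
                      seed = 1L) {
  if (k_true < 1 || length(topic_word_dists) != k_true) {
    config_error("'topic_word_dists' must hold one distribution per topic",
                 field = "topic_word_dists")
  }
  for (i in seq_along(topic_word_dists)) {
    check_prob_map(topic_word_dists[[i]], sprintf("topic_word_dists[%d]", i))
  }
  check_prob_map(background_vocab_dist, "background_vocab_dist")
  stopifnot(length(doc_length_range) == 2,
            doc_length_range[1] >= 1,
            doc_length_range[2] >= doc_length_range[1])
  if (!is.null(planted_phrases)) {
    planted_phrases <- tibble::as_tibble(planted_phrases)
    stopifnot(all(c("mtg", "phrase", "prob") %in% names(planted_phrases)))
    nw <- lengths(strsplit(planted_phrases$phrase, "\\s+"))
    if (any(nw < 2 | nw > 4)) {
      config_error("planted phrases must have 2-4 words",
                   field = "planted_phrases")
    }
  }
  structure(list(
    k_true = as.integer(k_true), topic_word_dists = topic_word_dists,
    doc_length_range = as.integer(doc_length_range),
    planted_phrases = planted_phrases,
    background_vocab_dist = background_vocab_dist,
    question_ids = question_ids, seed = as.integer(seed)),
    class = "text_spec")
}

# three disjoint 50-word themes (adrenal emergency / fatigue-sleep /
# fertility-heredity-growth) plus a pool of generic words shared by all
# topics. Within-theme probabilities decay mildly (1/sqrt(rank)): these
# are content words layered over the generic vocabulary, so no single
# content word dominates a document the way function words do.
.theme_words <- list(
  c("adrenal", "crisis", "cortisol", "steroid", "dose",
    "hydrocortisone", "stress", "hospital", "replacement",
    "glucocorticoid", "circadian", "rhythm", "salt", "pressure", "blood",
    "collapse", "vomiting", "infection", "fever", "dizziness",
    "nausea", "ambulance", "tablet", "dosage", "gland", "kidney",
    "fludrocortisone", "prednisolone", "aldosterone", "shock",
    "dehydration", "sodium", "potassium", "adrenaline", "fainting",
    "sick", "flu", "vaccination", "travel", "alert", "bracelet",
    "card", "protocol", "paramedic", "ward", "admission", "recovery",
    "relapse", "monitoring", "cortisone"),
  c("tired", "fatigue", "sleep", "energy", "exhausted", "rest", "night",
    "insomnia", "nap", "concentration", "brain", "fog", "morning",
    "wake", "daytime", "drowsy", "weakness", "muscle", "pain", "joint",
    "ache", "headache", "memory", "focus", "mood", "depression",
    "anxiety", "irritability", "motivation", "apathy", "heaviness",
    "stamina", "exercise", "walking", "stairs", "housework", "bedtime",
    "alarm", "snooze", "dream", "restless", "leg", "cramp", "stiffness",
    "slowness", "burnout", "overload", "recharge", "doze", "lethargy"),
  c("fertility", "pregnancy", "child", "heredity", "gene", "inheritance",
    "family", "puberty", "hormone", "growth", "development", "mutation",
    "genetic", "counselling", "conception", "ivf", "testosterone",
    "estrogen", "cycle", "ovary", "sperm", "embryo", "carrier",
    "screening", "syndrome", "chromosome", "dna", "parent", "sibling",
    "daughter", "son", "generation", "height", "weight", "bone",
    "maturation", "adolescence", "menstruation", "menopause",
    "contraception", "adoption", "donor", "miscarriage", "infertility",
    "testis", "uterus", "pediatrician", "clinic", "specialist",
    "andrologist"))
.generic_words <- c(
  "research", "disease", "doctor", "treatment", "medication", "life",
  "quality", "help", "important", "future", "worry", "hope", "care",
  "symptom", "condition", "patient", "information", "support", "effect",
  "therapy", "question", "answer", "time", "year", "problem")

#' @rdname text_spec
#' @export
default_topic_word_dists <- function(k_true = 3) {
  stopifnot(k_true >= 1, k_true <= length(.theme_words))
  lapply(seq_len(k_true), function(i) {
    specific <- .theme_words[[i]]
    p_spec <- 1 / sqrt(seq_along(specific))
    p_spec <- 0.75 * p_spec / sum(p_spec)
    p_gen <- rep(0.25 / length(.generic_words), length(.generic_words))
    setNames(c(p_spec, p_gen), c(specific, .generic_words))
  })
}

#' @rdname text_spec
#' @export
default_background_dist <- function() {
  # generic everyday vocabulary, mostly disjoint from the survey themes
  words <- c(.generic_words,
             "city", "road", "house", "school", "music", "history", "river",
             "mountain", "country", "language", "book", "game", "team",
             "player", "season", "film", "station", "company", "market",
             "government", "university", "student", "water", "food",
             "animal", "plant", "island", "church", "bridge", "train")
  p <- 1 / seq_along(words)
  setNames(p / sum(p), words)
}

#' Generate synthetic open-text answers for a cohort
#'
#' One document per respondent per open question. Each respondent is
#' assigned one latent topic; their documents are bags of words sampled
#' from that topic's distribution. Planted phrases are inserted verbatim
#' (as consecutive tokens at a random position) into documents of the
#' matching MTG with the stated probability.
#'
#' @param spec A [text_spec()].
#' @param cohort A non-empty cohort tibble from [generate_cohort()].
#' @return A document tibble (`respondent_id`, `question_id`, `mtg`,
#'   `text`).
#' @export
generate_open_text <- function(spec, cohort) {
  stopifnot(inherits(spec, "text_spec"))
  if (nrow(cohort) == 0) {
    config_error("cohort must be non-empty", field = "cohort")
  }
  if (any(lengths(spec$topic_word_dists) == 0)) {
    config_error("empty vocabulary in topic_word_dists",
                 field = "topic_word_dists")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(spec$seed, "text"))

  n <- nrow(cohort)
  topic_of <- sample.int(spec$k_true, n, replace = TRUE)
  rows <- vector("list", n * length(spec$question_ids))
  idx <- 1L
  for (i in seq_len(n)) {
    dist <- spec$topic_word_dists[[topic_of[i]]]
    for (q in spec$question_ids) {
      len <- sample(seq(spec$doc_length_range[1], spec$doc_length_range[2]), 1)
      words <- sample(names(dist), len, replace = TRUE, prob = dist)
      if (!is.null(spec$planted_phrases)) {
        pp <- spec$planted_phrases[spec$planted_phrases$mtg == cohort$mtg[i], ,
                                   drop = FALSE]
        if (nrow(pp) > 0) {
          for (j in seq_len(nrow(pp))) {
            if (runif(1) < pp$prob[j]) {
              at <- sample.int(length(words) + 1L, 1) - 1L
              words <- append(words, strsplit(pp$phrase[j], "\\s+")[[1]],
                              after = at)
            }
          }
        }
      }
      rows[[idx]] <- tibble::tibble(
        respondent_id = cohort$respondent_id[i], question_id = q,
        mtg = cohort$mtg[i], text = paste(words, collapse = " "))
      idx <- idx + 1L
    }
  }
  dplyr::bind_rows(rows)
}

#' Generate a desk-scale background corpus
#'
#' A stream of tokens drawn from the background vocabulary distribution,
#' broken into lines of roughly 50 tokens (one document per line) — a
#' stand-in, at test scale, for a large generic text collection against
#' which survey-specific terms stand out.
#'
#' @param spec A [text_spec()].
#' @param n_tokens Total token count (>= 1000).
#' @return Character vector of lines.
#' @export
generate_background_corpus <- function(spec, n_tokens = 50000) {
  stopifnot(inherits(spec, "text_spec"))
  if (n_tokens < 1000) {
    config_error("'n_tokens' must be >= 1000", field = "n_tokens")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(spec$seed, "background"))
  dist <- spec$background_vocab_dist
  toks <- sample(names(dist), n_tokens, replace = TRUE, prob = dist)
  starts <- seq(1, n_tokens, by = 50)
  vapply(starts, function(s) {
    paste(toks[s:min(s + 49, n_tokens)], collapse = " ")
  }, character(1))
}

#' Write a cohort table as CSV
#'
#' UTF-8, header row, one respondent per row; free-text fields are quoted.
#'
#' @param cohort Cohort tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_responses <- function(cohort, path) {
  readr::write_csv(cohort, path, na = "")
  invisible(path)
}
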