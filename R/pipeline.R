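#' Validate a pipeline run configuration
#'
#' A run configuration (R list or YAML file) names the inputs and the
#' analysis parameters of one reproducible pipeline run. Referenced paths
#' must resolve at validation time and every seed is explicit — there is
#' no wall-clock seeding anywhere in the pipeline.
#'
#' Fields: `responses` (CSV path) or `simulate` (list with
#' `n_respondents` and optional generator overrides), `background` (path
#' to a plain-text background corpus, one document per line; omitted if
#' `simulate` is used, the generator supplies one), `out_dir`,
#' `question_ids`, `k_range`, `gamma`, `stats_by`, `seed`, optional
#' `exclusions` (list of rule specs with country/mtg/keywords/label).
#'
#' @param config List or path to a YAML file.
#' @return The validated config list (class `run_config`).
#' @export
run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) {
      config_error(paste0("config file not found: ", config),
                   field = "config")
    }
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- list(question_ids = c("q_night", "q_research"),
                   k_range = 2:6, gamma = 0.8, stats_by = "mtg",
                   seed = 1L, background_tokens = 50000)
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  if (is.null(config$out_dir)) {
    config_error("config must name 'out_dir'", field = "out_dir")
  }
  if (is.null(config$responses) && is.null(config$simulate)) {
    config_error("config must provide 'responses' or 'simulate'",
                 field = "responses")
  }
  if (!is.null(config$responses) && !file.exists(config$responses)) {
    config_error(paste0("responses file not found: ", config$responses),
                 field = "responses")
  }
  if (!is.null(config[["background"]]) && !file.exists(config[["background"]])) {
    config_error(paste0("background corpus not found: ", config[["background"]]),
                 field = "background")
  }
  if (is.null(config[["background"]]) && is.null(config$simulate)) {
    config_error("a background corpus is required when not simulating",
                 field = "background")
  }
  if (config$gamma < 0 || config$gamma > 1) {
    config_error("'gamma' must be in [0, 1]", field = "gamma")
  }
  class(config) <- c("run_config", "list")
  config
}

parse_rules <- function(specs) {
  lapply(specs, function(s) {
    exclusion_rule(country = s$country, mtg = s$mtg,
                   keywords = s$keywords %||% character(),
                   label = s$label %||% "exclusion")
  })
}

write_stage <- function(x, dir, name) {
  path <- file.path(dir, name)
  readr::write_csv(x, path, na = "")
  path
}

#' Run the full survey-analysis pipeline
#'
#' Executes ingest (or simulation), exclusion rules, demographic summary,
#' priority-rating statistics, corpus preparation, topic modelling with
#' automatic selection of k, and per-group KLIP phrase extraction, in
#' that order. Each stage's outputs are written to `out_dir` so stages
#' can be inspected and re-run independently; a manifest with the MD5
#' hash of every output file is written last. A rerun with identical
#' config and inputs yields byte-identical manifest hashes. Inputs are
#' never mutated.
#'
#' @param config A [run_config()] (or list / YAML path coercible to one).
#' @return A `report_bundle`: list with `demographics`, `summaries`,
#'   `ranking`, `tests` (paired-topic family, per-topic ANOVA + post-hoc),
#'   `gender_contrast`, `k_selection`, `topics`, `phrases` (per group),
#'   `audit`, `manifest`.
#' @export
run_pipeline <- function(config) {
  config <- run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)

  # -- ingest or simulate ----------------------------------------------
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    sim$seed <- seed
    cspec <- do.call(cohort_spec, sim[names(sim) %in%
      names(formals(cohort_spec))])
    records <- generate_cohort(cspec)
    tspec <- text_spec(seed = seed,
                       planted_phrases = default_planted_phrases())
    docs_raw <- generate_open_text(tspec, records)
    bg_lines <- if (!is.null(config[["background"]])) {
      readLines(config[["background"]], encoding = "UTF-8")
    } else {
      generate_background_corpus(tspec, config[["background_tokens"]])
    }
    # attach open answers to the record table for exclusion matching
    for (q in unique(docs_raw$question_id)) {
      qd <- docs_raw[docs_raw$question_id == q, ]
      records[[q]] <- qd$text[match(records$respondent_id,
                                    qd$respondent_id)]
    }
  } else {
    records <- load_responses(config$responses, schema = config$schema)
    bg_lines <- readLines(config[["background"]], encoding = "UTF-8")
    docs_raw <- NULL
  }

  # -- exclusions -------------------------------------------------------
  rules <- parse_rules(config$exclusions %||% list())
  excl <- apply_exclusions(records, rules)
  records <- excl$kept
  if (nrow(records) == 0) {
    abort("no records left after exclusions [stage: exclusions]",
          class = "endovoices_config_error")
  }

  # -- quantitative arm -------------------------------------------------
  demo <- demographic_summary(records)
  summaries <- summarise_all_ratings(records)
  ranking <- rank_topics(summaries)
  paired <- paired_t_family(records)
  by <- config$stats_by
  anova_rows <- list()
  posthoc_rows <- list()
  for (tp in priority_topics()) {
    groups <- ratings_by_group(records, tp, by = by)
    groups <- lapply(groups, function(x) x[!is.na(x)])
    groups <- groups[lengths(groups) >= 2]
    if (length(groups) < 2) next
    a <- one_way_anova(groups)
    a$topic <- tp
    anova_rows[[tp]] <- a
    ph <- posthoc_pairwise(groups)
    ph$topic <- tp
    posthoc_rows[[tp]] <- ph
  }
  tests <- dplyr::bind_rows(
    paired,
    dplyr::bind_rows(anova_rows),
    dplyr::bind_rows(posthoc_rows))
  gender <- gender_contrast(records)

  # -- text arm ---------------------------------------------------------
  if (is.null(docs_raw)) {
    qcols <- grep("^q_", names(records), value = TRUE)
    docs_raw <- tidyr::pivot_longer(
      records[, c("respondent_id", "mtg", qcols)],
      dplyr::all_of(qcols), names_to = "question_id", values_to = "text")
    docs_raw <- docs_raw[!is.na(docs_raw$text) & nzchar(docs_raw$text), ]
  }
  docs <- prepare_documents(docs_raw)
  docs <- combine_questions(docs, config$question_ids)
  tw <- build_tfidf(docs)
  emb <- train_embeddings(docs, seed = seed)
  sel <- select_k(tw, k_range = config$k_range, embeddings = emb,
                  seed = seed)
  best <- sel$models[[as.character(sel$k_star)]]
  topics_tbl <- dplyr::bind_rows(lapply(seq_len(best$k), function(j) {
    tibble::tibble(topic_id = j,
                   top_words = paste(best$top_words[[j]], collapse = ", "),
                   coherence = best$coherence_per_topic[j])
  }))
  bg <- background_corpus(bg_lines)
  phrases <- klip_by_group(docs, bg, gamma = config$gamma)

  # -- reports and manifest --------------------------------------------
  out <- config$out_dir
  files <- c(
    write_stage(demo, out, "demographics.csv"),
    write_stage(summaries, out, "rating_summaries.csv"),
    write_stage(ranking, out, "topic_ranking.csv"),
    write_stage(tests, out, "stat_tests.csv"),
    write_stage(gender, out, "gender_contrast.csv"),
    write_stage(sel$coherence, out, "coherence_by_k.csv"),
    write_stage(topics_tbl, out, "topics.csv"))
  for (g in names(phrases)) {
    safe <- gsub("[^A-Za-z0-9]+", "_", g)
    p <- phrases[[g]]
    p$respondents <- NULL
    files <- c(files, write_stage(p, out, paste0("phrases_", safe, ".csv")))
  }
  files <- c(files, write_stage(excl$audit, out, "exclusion_audit.csv"))
  manifest <- tibble::tibble(
    file = basename(files),
    md5 = unname(tools::md5sum(files)))
  jsonlite::write_json(
    list(seed = seed, significance_threshold = 0.05,
         gamma = config$gamma, k_star = sel$k_star,
         files = manifest),
    file.path(out, "manifest.json"), auto_unbox = TRUE, digits = NA)

  structure(list(demographics = demo, summaries = summaries,
                 ranking = ranking, tests = tests,
                 gender_contrast = gender, k_selection = sel,
                 topics = topics_tbl, phrases = phrases,
                 audit = excl$audit, manifest = manifest,
                 config = config),
            class = "report_bundle")
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf("pipeline report: %d respondents, k = %d, %d phrase group(s)\n",
              sum(x$demographics$count[x$demographics$category == "gender"]),
              x$k_selection$k_star, length(x$phrases)))
  invisible(x)
}

#' Default planted phrases used by simulated runs
#'
#' One distinctive multi-word phrase per disease group, inserted into
#' that group's documents with probability 0.6 — the ground truth that
#' per-group phrase extraction is expected to recover. The phrase words
#' are deliberately outside the planted topic vocabularies, so a phrase
#' marks its group the way disease-specific jargon marks real responses.
#'
#' @return Tibble with columns `mtg`, `phrase`, `prob`.
#' @export
default_planted_phrases <- function() {
  tibble::tibble(
    mtg = mtg_labels(),
    phrase = c("emergency injection", "calcium level", "insulin pump",
               "tumour surveillance", "appetite control",
               "pituitary surgery", "hearing loss", "slow release"),
    prob = 0.6)
}
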