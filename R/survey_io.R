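#' Read survey responses from a delimited text file
#'
#' Reads a CSV/TSV response table, optionally remapping column names via a
#' schema, coercing ratings to integers and collecting every row-level
#' problem in a validation report instead of failing. A rating outside
#' \{1, 2, 3\} or unparseable is recorded as absent and reported; unknown
#' MTG, gender, age-band or country values are retained verbatim but
#' reported. Rows are never silently dropped.
#'
#' @param path Path to a CSV (or TSV if `delim = "\t"`) file with header.
#' @param schema Optional list with element `columns`, a named character
#'   vector mapping file column names to canonical names
#'   (`respondent_id`, `gender`, `age_band`, `country`, `mtg`,
#'   `is_member`, `role`, the nine `rating_*` columns, and `q_*` open-text
#'   columns). May be a path to a YAML file with the same structure.
#' @param delim Field delimiter, default ",".
#' @return A tibble of responses with a `"validation"` attribute (tibble:
#'   `row`, `field`, `value`, `message`); see [validation_report()].
#' @export
load_responses <- function(path, schema = NULL, delim = ",") {
  if (!file.exists(path)) {
    schema_error(paste0("response file not found: ", path))
  }
  if (is.character(schema) && length(schema) == 1) {
    schema <- yaml::read_yaml(schema)
  }
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()), na = character(),
    show_col_types = FALSE)
  if (!is.null(schema$columns)) {
    m <- unlist(schema$columns)
    hit <- names(raw) %in% names(m)
    names(raw)[hit] <- unname(m[names(raw)[hit]])
  }
  mandatory <- c("respondent_id", "gender", "age_band", "country", "mtg",
                 "is_member", "role")
  missing_cols <- setdiff(mandatory, names(raw))
  if (length(missing_cols) > 0) {
    schema_error(paste0("missing mandatory column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  report <- list()
  note <- function(row, field, value, message) {
    report[[length(report) + 1]] <<- tibble::tibble(
      row = row, field = field, value = as.character(value),
      message = message)
  }
  out <- raw
  out$is_member <- tolower(raw$is_member) %in% c("true", "t", "1", "yes")
  for (tp in priority_topics()) {
    col <- rating_col(tp)
    if (!col %in% names(out)) next
    v <- suppressWarnings(as.integer(out[[col]]))
    blank <- !nzchar(trimws(out[[col]]))
    bad <- !blank & (is.na(v) | !(v %in% 1:3))
    for (i in which(bad)) {
      note(i, col, out[[col]][i], "rating outside 1-3 recorded as absent")
    }
    v[bad | blank] <- NA_integer_
    out[[col]] <- v
  }
  for (i in which(!out$mtg %in% mtg_labels())) {
    note(i, "mtg", out$mtg[i], "unknown MTG label")
  }
  for (i in which(!out$gender %in% gender_labels())) {
    note(i, "gender", out$gender[i], "unknown gender label")
  }
  for (i in which(!out$age_band %in% age_bands())) {
    note(i, "age_band", out$age_band[i], "unknown age band")
  }
  known <- known_countries()
  for (i in which(!tolower(out$country) %in% known)) {
    note(i, "country", out$country[i], "unknown country")
  }
  rep_tbl <- if (length(report) > 0) {
    dplyr::bind_rows(report)
  } else {
    tibble::tibble(row = integer(0), field = character(0),
                   value = character(0), message = character(0))
  }
  if (nrow(rep_tbl) > 0) {
    warn(sprintf("%d validation issue(s) while reading %s",
                 nrow(rep_tbl), path))
  }
  attr(out, "validation") <- rep_tbl
  out
}

#' @rdname load_responses
#' @param records A tibble returned by [load_responses()].
#' @export
validation_report <- function(records) {
  attr(records, "validation") %||%
    tibble::tibble(row = integer(0), field = character(0),
                   value = character(0), message = character(0))
}

region_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "un_regions.csv", package = "endovoices")
      tbl <- readr::read_csv(path, col_types = "cccc", na = character(),
                             show_col_types = FALSE)
      keys <- c(tolower(tbl$country), tolower(tbl$alpha2))
      regions <- c(tbl$region, tbl$region)
      for (i in seq_len(nrow(tbl))) {
        if (nzchar(tbl$aliases[i])) {
          al <- strsplit(tbl$aliases[i], "\\|")[[1]]
          keys <- c(keys, tolower(al))
          regions <- c(regions, rep(tbl$region[i], length(al)))
        }
      }
      cache <<- list(tbl = tbl, lookup = setNames(regions, keys))
    }
    cache
  }
})

known_countries <- function() names(region_table()$lookup)

#' Map a country to its reporting region
#'
#' Deterministic lookup against the shipped country table, which follows
#' the United Nations Statistics Division (M49) split of Europe into
#' Eastern, Northern, Southern and Western Europe; every other recognised
#' country maps to "Non-Europe". Country names, ISO-3166 alpha-2 codes and
#' common aliases are accepted, case-insensitively. An unrecognised
#' country raises an error — it is never silently binned as Non-Europe.
#'
#' @param country Character vector of country names or codes.
#' @return Character vector of regions (see [region_labels()]).
#' @export
map_region <- function(country) {
  lookup <- region_table()$lookup
  key <- tolower(trimws(country))
  hit <- lookup[key]
  if (anyNA(hit)) {
    bad <- unique(country[is.na(hit)])
    abort(paste0("unknown country: ", paste(bad, collapse = ", ")),
          class = "endovoices_unknown_country_error")
  }
  unname(hit)
}

#' Define a cohort exclusion rule
#'
#' A rule matches records by country and/or MTG; a matching record is
#' excluded *unless* any of the rule's keywords appears (case-insensitive
#' substring, checked on both raw and lemmatised text) in one of its open
#' answers. This makes reproducible the style of cleaning in which
#' responses from one country/disease-group stratum are kept only when
#' they specifically mention qualifying conditions.
#'
#' @param country Country to match, or NULL for any.
#' @param mtg MTG label to match, or NULL for any.
#' @param keywords Character vector; presence of any rescues the record.
#' @param label Audit label for the rule.
#' @return An `exclusion_rule` object.
#' @export
exclusion_rule <- function(country = NULL, mtg = NULL,
                           keywords = character(), label = "exclusion") {
  if (is.null(country) && is.null(mtg)) {
    config_error("an exclusion rule needs at least one of country or mtg",
                 field = "exclusion_rule")
  }
  structure(list(country = country, mtg = mtg,
                 keywords = tolower(keywords), label = label),
            class = "exclusion_rule")
}

#' Apply exclusion rules to a cohort
#'
#' @param records Response tibble (with `country`, `mtg` and any `q_*`
#'   open-text columns).
#' @param rules List of [exclusion_rule()] objects (may be empty).
#' @return List with `kept` (tibble) and `audit` (tibble of dropped
#'   `respondent_id` and rule `label`); `nrow(kept) + nrow(audit)` always
#'   equals `nrow(records)`.
#' @export
apply_exclusions <- function(records, rules = list()) {
  if (inherits(rules, "exclusion_rule")) rules <- list(rules)
  audit <- tibble::tibble(respondent_id = character(0), label = character(0))
  if (length(rules) == 0 || nrow(records) == 0) {
    return(list(kept = records, audit = audit))
  }
  qcols <- grep("^q_", names(records), value = TRUE)
  drop <- logical(nrow(records))
  drop_label <- character(nrow(records))
  for (rule in rules) {
    stopifnot(inherits(rule, "exclusion_rule"))
    match <- rep(TRUE, nrow(records))
    if (!is.null(rule$country)) {
      match <- match & tolower(records$country) == tolower(rule$country)
    }
    if (!is.null(rule$mtg)) {
      match <- match & records$mtg == rule$mtg
    }
    if (!any(match)) next
    rescued <- logical(nrow(records))
    if (length(rule$keywords) > 0 && length(qcols) > 0) {
      for (i in which(match)) {
        texts <- tolower(unlist(records[i, qcols], use.names = FALSE))
        texts <- texts[!is.na(texts)]
        lemmas <- vapply(texts, function(x) {
          paste(tokenize_lemmatize(x)$tokens, collapse = " ")
        }, character(1), USE.NAMES = FALSE)
        hay <- c(texts, lemmas)
        rescued[i] <- any(vapply(rule$keywords, function(k) {
          any(grepl(k, hay, fixed = TRUE))
        }, logical(1)))
      }
    }
    newly <- match & !rescued & !drop
    drop[newly] <- TRUE
    drop_label[newly] <- rule$label
  }
  audit <- tibble::tibble(respondent_id = records$respondent_id[drop],
                          label = drop_label[drop])
  list(kept = records[!drop, , drop = FALSE], audit = audit)
}

#' Demographic summary table
#'
#' Counts and percentages per category (gender, age band, MTG, region,
#' respondent role, advocacy-group membership), in the layout of a
#' standard cohort-description table. Percent = 100 * count / total,
#' rounded half-up to one decimal. Region is derived from country via
#' [map_region()]. Invariant under permutation of the input rows.
#'
#' @param records Non-empty response tibble.
#' @return Tibble with columns `category`, `label`, `count`, `percent`.
#' @export
demographic_summary <- function(records) {
  if (nrow(records) == 0) {
    abort("cannot summarise an empty cohort",
          class = "endovoices_config_error")
  }
  total <- nrow(records)
  one <- function(category, values, levels) {
    values <- factor(values, levels = levels)
    cnt <- table(values)
    tibble::tibble(
      category = category, label = names(cnt),
      count = as.integer(cnt),
      percent = round_half_up(100 * as.integer(cnt) / total, 1))
  }
  region <- map_region(records$country)
  member <- ifelse(records$is_member, "member", "non-member")
  dplyr::bind_rows(
    one("gender", records$gender, gender_labels()),
    one("age_band", records$age_band, age_bands()),
    one("mtg", records$mtg, mtg_labels()),
    one("region", region, region_labels()),
    one("role", records$role, role_labels()),
    one("membership", member, c("member", "non-member")))
}
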