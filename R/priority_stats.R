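#' Summarise the ratings of one priority topic
#'
#' Mean and sample standard deviation (n - 1 denominator) over the
#' non-missing ratings, as printed in cohort tables of the form
#' "1.26 +/- 0.57". Lower mean = higher priority on the 3-point scale.
#'
#' @param records Response tibble with `rating_*` columns.
#' @param topic One of [priority_topics()].
#' @return One-row tibble: `topic`, `n`, `mean`, `sd`.
#' @export
summarise_ratings <- function(records, topic) {
  if (!topic %in% priority_topics()) {
    config_error(paste0("unknown topic: ", topic), field = "topic")
  }
  r <- records[[rating_col(topic)]]
  r <- r[!is.na(r)]
  if (length(r) == 0) {
    abort(paste0("all ratings missing for topic: ", topic),
          class = "endovoices_config_error")
  }
  tibble::tibble(topic = topic, n = length(r), mean = mean(r),
                 sd = if (length(r) > 1) sd(r) else 0)
}

#' @rdname summarise_ratings
#' @export
summarise_all_ratings <- function(records) {
  dplyr::bind_rows(lapply(priority_topics(), function(tp) {
    summarise_ratings(records, tp)
  }))
}

# df is stored as character ("19", "2,12", "31.7") so paired, two-sample
# and F rows stack into one report table
stat_row <- function(kind, comparison, statistic, df, p_raw,
                     p_adjusted = NA_real_, m = NA_integer_,
                     degenerate = FALSE) {
  tibble::tibble(kind = kind, comparison = comparison,
                 statistic = statistic, df = as.character(df), p_raw = p_raw,
                 p_adjusted = p_adjusted, m = m, degenerate = degenerate)
}

#' Paired t-test between two priority topics
#'
#' Computed on the complete-pairs subset (respondents with both ratings
#' present): t = mean(d) / (sd(d) / sqrt(n)) with df = n - 1 and a
#' two-sided p from Student's t distribution. When the differences have
#' zero variance the test is degenerate and flagged: p = 1 if the mean
#' difference is also zero (identical columns), p = 0 otherwise (constant
#' nonzero shift).
#'
#' @inheritParams summarise_ratings
#' @param topic_a,topic_b Topics to compare.
#' @return One-row test tibble (`kind`, `comparison`, `statistic`, `df`,
#'   `p_raw`, `p_adjusted`, `m`, `degenerate`).
#' @export
paired_t <- function(records, topic_a, topic_b) {
  a <- records[[rating_col(topic_a)]]
  b <- records[[rating_col(topic_b)]]
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  cmp <- paste(topic_a, "vs", topic_b)
  if (length(a) < 2) {
    abort(paste0("fewer than 2 complete pairs for ", cmp),
          class = "endovoices_config_error")
  }
  d <- a - b
  n <- length(d)
  if (sd(d) == 0) {
    if (mean(d) == 0) {
      return(stat_row("paired_t", cmp, 0, n - 1, 1, degenerate = TRUE))
    }
    return(stat_row("paired_t", cmp, sign(mean(d)) * Inf, n - 1, 0,
                    degenerate = TRUE))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  stat_row("paired_t", cmp, unname(tt$statistic), unname(tt$parameter),
           tt$p.value)
}

#' All-pairs paired t-tests over the nine topics
#'
#' The 36 between-topic paired tests, with both raw and
#' Bonferroni-adjusted p-values (m = 36) reported.
#'
#' @inheritParams summarise_ratings
#' @return Test tibble, one row per unordered topic pair.
#' @export
paired_t_family <- function(records) {
  tps <- priority_topics()
  pairs <- combn(tps, 2)
  res <- dplyr::bind_rows(lapply(seq_len(ncol(pairs)), function(j) {
    paired_t(records, pairs[1, j], pairs[2, j])
  }))
  res$m <- ncol(pairs)
  res$p_adjusted <- bonferroni(res$p_raw, ncol(pairs))
  res
}

#' Bonferroni adjustment
#'
#' `p_adjusted = min(1, m * p_raw)`, monotone non-decreasing in m.
#'
#' @param p Raw p-values.
#' @param m Number of comparisons in the family.
#' @return Adjusted p-values.
#' @export
bonferroni <- function(p, m) pmin(1, m * p)

#' One-way analysis of variance across groups
#'
#' F = MS_between / MS_within with df = (g - 1, N - g); p from the F
#' distribution. With zero within-group variance everywhere and equal
#' means the statistic is undefined and the result is flagged degenerate
#' (F = 0, p = 1 by convention); unequal means with zero within-variance
#' give a degenerate F = Inf, p = 0.
#'
#' @param groups Named list, group label -> numeric ratings (NAs dropped);
#'   at least 2 groups with >= 2 observations each.
#' @return One-row test tibble.
#' @export
one_way_anova <- function(groups) {
  groups <- lapply(groups, function(x) x[!is.na(x)])
  groups <- groups[lengths(groups) > 0]
  if (length(groups) < 2 || any(lengths(groups) < 2)) {
    abort("one-way ANOVA needs >= 2 groups with >= 2 observations each",
          class = "endovoices_config_error")
  }
  g <- length(groups)
  n <- lengths(groups)
  N <- sum(n)
  means <- vapply(groups, mean, numeric(1))
  grand <- sum(unlist(groups)) / N
  ss_between <- sum(n * (means - grand)^2)
  ss_within <- sum(vapply(groups, function(x) sum((x - mean(x))^2),
                          numeric(1)))
  cmp <- paste(names(groups), collapse = " | ")
  df1 <- g - 1; df2 <- N - g
  if (ss_within == 0) {
    if (ss_between == 0) {
      return(stat_row("anova_F", cmp, 0, paste(df1, df2, sep = ","), 1,
                      degenerate = TRUE))
    }
    return(stat_row("anova_F", cmp, Inf, paste(df1, df2, sep = ","), 0,
                    degenerate = TRUE))
  }
  f <- (ss_between / df1) / (ss_within / df2)
  stat_row("anova_F", cmp, f, paste(df1, df2, sep = ","),
           pf(f, df1, df2, lower.tail = FALSE))
}

two_sample_t <- function(x, y, cmp, pooled = FALSE) {
  if (sd(x) == 0 && sd(y) == 0) {
    if (mean(x) == mean(y)) {
      return(stat_row("welch_t", cmp, 0, length(x) + length(y) - 2, 1,
                      degenerate = TRUE))
    }
    return(stat_row("welch_t", cmp, sign(mean(x) - mean(y)) * Inf,
                    length(x) + length(y) - 2, 0, degenerate = TRUE))
  }
  tt <- stats::t.test(x, y, var.equal = pooled)
  stat_row(if (pooled) "pooled_t" else "welch_t", cmp,
           unname(tt$statistic), unname(tt$parameter), tt$p.value)
}

#' Post-hoc pairwise t-tests with Bonferroni correction
#'
#' All g(g-1)/2 pairwise two-sample t-tests between the groups of a
#' preceding one-way ANOVA; `p_adjusted = min(1, m * p_raw)` with m the
#' number of pairs. Welch's unequal-variance t is the default (group
#' sizes in such cohorts are highly unequal); a pooled-variance t is
#' available. Results ordered by comparison label; degenerate pairs are
#' flagged, never dropped.
#'
#' @inheritParams one_way_anova
#' @param var Variance handling: "welch" (default) or "pooled".
#' @return Test tibble with one row per pair.
#' @export
posthoc_pairwise <- function(groups, var = c("welch", "pooled")) {
  var <- match.arg(var)
  groups <- lapply(groups, function(x) x[!is.na(x)])
  groups <- groups[lengths(groups) >= 2]
  labs <- sort(names(groups))
  if (length(labs) < 2) {
    abort("post-hoc tests need >= 2 groups", class = "endovoices_config_error")
  }
  pairs <- combn(labs, 2)
  m <- ncol(pairs)
  res <- dplyr::bind_rows(lapply(seq_len(m), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    two_sample_t(groups[[a]], groups[[b]], paste(a, "vs", b),
                 pooled = (var == "pooled"))
  }))
  res$m <- m
  res$p_adjusted <- bonferroni(res$p_raw, m)
  res[order(res$comparison), , drop = FALSE]
}

#' Group ratings of one topic by a factor
#'
#' Convenience splitter feeding [one_way_anova()] and
#' [posthoc_pairwise()].
#'
#' @inheritParams summarise_ratings
#' @param by Grouping column, e.g. "mtg", "gender" or "region".
#' @return Named list of numeric rating vectors.
#' @export
ratings_by_group <- function(records, topic, by = "mtg") {
  v <- records[[rating_col(topic)]]
  g <- if (by == "region") map_region(records$country) else records[[by]]
  split(v, g)
}

#' Two-sample gender contrast for one topic
#'
#' Run as an independent two-sample test outside the between-MTG family
#' (so no Bonferroni adjustment from that family applies). Respondents
#' with undisclosed gender are excluded from the contrast.
#'
#' @inheritParams summarise_ratings
#' @param var See [posthoc_pairwise()].
#' @return One-row test tibble.
#' @export
gender_contrast <- function(records, topic = "fertility",
                            var = c("welch", "pooled")) {
  var <- match.arg(var)
  g <- ratings_by_group(records, topic, by = "gender")
  f <- g[["female"]]; m <- g[["male"]]
  f <- f[!is.na(f)]; m <- m[!is.na(m)]
  two_sample_t(f, m, paste0("female vs male (", topic, ")"),
               pooled = (var == "pooled"))
}

#' Rank topics by priority
#'
#' Ascending by mean rating (lower mean = more important). Ties are
#' broken lexicographically on the topic label and flagged.
#'
#' @param summaries Tibble from [summarise_all_ratings()].
#' @return Tibble of `rank`, `topic`, `mean`, `tie` (logical).
#' @export
rank_topics <- function(summaries) {
  o <- order(summaries$mean, summaries$topic)
  s <- summaries[o, , drop = FALSE]
  tie <- duplicated(s$mean) | duplicated(s$mean, fromLast = TRUE)
  tibble::tibble(rank = seq_len(nrow(s)), topic = s$topic, mean = s$mean,
                 tie = tie)
}
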