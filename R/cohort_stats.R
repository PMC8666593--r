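# Accept a column given as a bare name, a string, or a variable holding a
# string (for programmatic callers like the stats battery).
resolve_col <- function(q, table, what) {
  nm <- tryCatch(as_name(q), error = function(e) NA_character_)
  if (!is.na(nm) && nm %in% names(table)) return(nm)
  val <- tryCatch(rlang::eval_tidy(q), error = function(e) NULL)
  if (is.character(val) && length(val) == 1 && val %in% names(table)) return(val)
  abort(sprintf("Column for `%s` not found in `table`.", what))
}

#' Two-group one-way ANOVA comparison of a cohort metric
#'
#' Compares a numeric metric across a binary grouping (e.g. pressure-injury
#' history, presence of spasms) with a one-way ANOVA. Rows with a missing
#' metric or group label are dropped pairwise. For two groups the ANOVA is
#' algebraically the pooled two-sided t test (F = t^2), and the 95% CI of the
#' group-mean difference is the pooled-variance t interval, consistent with
#' the ANOVA's equal-variance assumption. The reported difference is
#' mean(first group level) - mean(second group level), levels sorted.
#'
#' @param table Cohort data frame (one row per subject).
#' @param metric Metric column (bare name or string).
#' @param group Binary grouping column (bare name or string).
#' @param conf_level Confidence level for the difference CI (default 0.95).
#' @return An object of class `group_comparison`; see [tidy.group_comparison()]
#'   and [glance.group_comparison()].
#' @examples
#' tb <- tibble::tibble(y = c(1, 2, 3, 2, 3, 4), g = rep(0:1, each = 3))
#' glance(group_compare(tb, y, g))
#' @export
group_compare <- function(table, metric, group, conf_level = 0.95) {
  metric_nm <- resolve_col(enquo(metric), table, "metric")
  group_nm <- resolve_col(enquo(group), table, "group")
  y <- table[[metric_nm]]; g <- table[[group_nm]]
  ok <- !is.na(y) & !is.na(g)
  y <- y[ok]; g <- g[ok]
  levels <- sort(unique(g))
  if (length(levels) != 2) {
    abort(sprintf("`%s` must have exactly 2 non-missing levels (found %d).",
                  group_nm, length(levels)))
  }
  y1 <- y[g == levels[1]]; y2 <- y[g == levels[2]]
  if (length(y1) < 2 || length(y2) < 2) {
    abort("Each group needs at least 2 non-missing values.")
  }
  fit <- anova(lm(y ~ factor(g)))
  tt <- t.test(y1, y2, var.equal = TRUE, conf.level = conf_level)
  groups <- tibble(
    level = levels,
    n = c(length(y1), length(y2)),
    mean = c(mean(y1), mean(y2)),
    sd = c(sd(y1), sd(y2))
  )
  structure(list(
    metric = metric_nm, group = group_nm, groups = groups,
    difference = mean(y1) - mean(y2),
    conf.low = tt$conf.int[1], conf.high = tt$conf.int[2],
    conf.level = conf_level,
    statistic = fit$`F value`[1], p.value = fit$`Pr(>F)`[1],
    df = unname(fit$Df), n = length(y)
  ), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s by %s\n", x$metric, x$group))
  print(x$groups)
  cat(sprintf("  difference %.4g [%.4g, %.4g], F(%d,%d) = %.4g, p = %.4g\n",
              x$difference, x$conf.low, x$conf.high, x$df[1], x$df[2],
              x$statistic, x$p.value))
  invisible(x)
}

#' Tidy a group comparison
#'
#' @param x A `group_comparison`.
#' @param ... Unused.
#' @return One row per group level: `level`, `n`, `mean`, `sd`.
#' @exportS3Method generics::tidy
tidy.group_comparison <- function(x, ...) {
  mutate(x$groups, metric = x$metric, group = x$group, .before = 1)
}

#' One-row summary of a group comparison
#'
#' @param x A `group_comparison`.
#' @param ... Unused.
#' @return One-row tibble: metric, group, per-level ns, difference with CI,
#'   F statistic and p value.
#' @exportS3Method generics::glance
glance.group_comparison <- function(x, ...) {
  tibble(
    metric = x$metric, group = x$group,
    n = x$n, n1 = x$groups$n[1], n2 = x$groups$n[2],
    mean1 = x$groups$mean[1], mean2 = x$groups$mean[2],
    estimate = x$difference, conf.low = x$conf.low, conf.high = x$conf.high,
    statistic = x$statistic, p.value = x$p.value
  )
}

#' Pearson correlation between two cohort columns
#'
#' Pairwise-complete Pearson correlation with its two-sided p value, used for
#' the continuous covariate and biomechanical-risk associations.
#'
#' @param table Cohort data frame.
#' @param x,y Numeric columns (bare names or strings).
#' @return One-row tibble: `x`, `y`, `n`, `estimate` (r), `conf.low`,
#'   `conf.high`, `statistic` (t), `p.value`.
#' @examples
#' tb <- tibble::tibble(a = 1:4, b = c(2, 1, 4, 3))
#' correlate(tb, a, b)$estimate  # 0.6
#' @export
correlate <- function(table, x, y) {
  x_nm <- resolve_col(enquo(x), table, "x")
  y_nm <- resolve_col(enquo(y), table, "y")
  xv <- table[[x_nm]]; yv <- table[[y_nm]]
  ok <- !is.na(xv) & !is.na(yv)
  xv <- xv[ok]; yv <- yv[ok]
  if (length(xv) < 3) abort("Need at least 3 complete pairs.")
  if (sd(xv) == 0 || sd(yv) == 0) {
    abort("Zero variance in a column; the correlation is undefined.")
  }
  ct <- suppressWarnings(cor.test(xv, yv, method = "pearson"))
  tibble(x = x_nm, y = y_nm, n = length(xv),
         estimate = unname(ct$estimate),
         conf.low = if (!is.null(ct$conf.int)) ct$conf.int[1] else NA_real_,
         conf.high = if (!is.null(ct$conf.int)) ct$conf.int[2] else NA_real_,
         statistic = unname(ct$statistic), p.value = ct$p.value)
}

#' Exclude fully fat-infiltrated subjects
#'
#' A negative IMAT effect size means the gluteus maximus is brighter than the
#' reference adipose, i.e. the muscle is indistinguishable from fat (complete
#' infiltration). This filter removes those subjects; the boundary value 0 is
#' kept. Rows with a missing IMAT effect size are retained.
#'
#' @param table Cohort data frame with an `imat_effect_size` column.
#' @return The filtered table (a tibble); the number of removed rows is
#'   reported via `message()` and stored in attribute `n_excluded`.
#' @export
exclude_full_infiltration <- function(table) {
  if (!"imat_effect_size" %in% names(table)) {
    abort("`table` has no `imat_effect_size` column.")
  }
  drop <- !is.na(table$imat_effect_size) & table$imat_effect_size < 0
  out <- as_tibble(table[!drop, ])
  message(sprintf("Excluded %d fully fat-infiltrated subject(s) (IMAT effect size < 0).",
                  sum(drop)))
  if (nrow(out) == 0) warn("All subjects excluded; empty table returned.")
  attr(out, "n_excluded") <- sum(drop)
  out
}

#' Participant-characteristics summary table
#'
#' Per group and overall: mean (SD) and median (min-max) for continuous
#' columns, counts and percentages for categorical ones. The overall mean of
#' every continuous column equals the sample-size-weighted average of the
#' group means by construction (internal consistency of the summary).
#'
#' @param table Cohort data frame.
#' @param group Grouping column (bare name or string; default `pri_history`).
#' @param continuous,categorical Character vectors naming the columns to
#'   summarise; by default numeric columns with more than 2 distinct values
#'   are continuous and 2-level/logical columns are categorical.
#' @return A tibble with columns `variable`, `level` (NA for continuous),
#'   `group` ("all" plus each group level), `n`, `mean`, `sd`, `median`,
#'   `min`, `max`, `count`, `pct`. An SD over fewer than 2 values is `NA`.
#' @export
cohort_summary <- function(table, group = pri_history,
                           continuous = NULL, categorical = NULL) {
  group_nm <- resolve_col(enquo(group), table, "group")
  cand <- setdiff(names(table), c(group_nm, "subject_id", "seed"))
  if (is.null(continuous) || is.null(categorical)) {
    is_cat <- vapply(cand, function(nm) {
      v <- table[[nm]]
      is.logical(v) || is.character(v) || is.factor(v) ||
        (is.numeric(v) && length(unique(v[!is.na(v)])) <= 2)
    }, logical(1))
    if (is.null(continuous)) {
      continuous <- cand[!is_cat & vapply(cand, function(nm) is.numeric(table[[nm]]), logical(1))]
    }
    if (is.null(categorical)) categorical <- cand[is_cat]
  }

  g <- table[[group_nm]]
  splits <- c(list(all = rep(TRUE, nrow(table))),
              setNames(lapply(sort(unique(g[!is.na(g)])), function(lv) !is.na(g) & g == lv),
                       paste0(group_nm, "=", sort(unique(g[!is.na(g)])))))

  rows <- list()
  for (v in continuous) {
    for (snm in names(splits)) {
      x <- table[[v]][splits[[snm]]]
      x <- x[!is.na(x)]
      if (!length(x)) next
      rows[[length(rows) + 1]] <- tibble(
        variable = v, level = NA_character_, group = snm, n = length(x),
        mean = mean(x), sd = if (length(x) >= 2) sd(x) else NA_real_,
        median = median(x), min = min(x), max = max(x),
        count = NA_integer_, pct = NA_real_)
    }
  }
  for (v in categorical) {
    for (snm in names(splits)) {
      x <- table[[v]][splits[[snm]]]
      x <- x[!is.na(x)]
      if (!length(x)) next
      for (lv in sort(unique(x))) {
        rows[[length(rows) + 1]] <- tibble(
          variable = v, level = as.character(lv), group = snm,
          n = length(x), mean = NA_real_, sd = NA_real_, median = NA_real_,
          min = NA_real_, max = NA_real_,
          count = sum(x == lv), pct = 100 * mean(x == lv))
      }
    }
  }
  bind_rows(rows)
}
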