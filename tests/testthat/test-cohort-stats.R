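test_that("two-group ANOVA matches the hand decomposition", {
  tb <- tibble::tibble(y = c(1, 2, 3, 2, 3, 4), g = rep(0:1, each = 3))
  gc <- group_compare(tb, y, g)
  orc <- oracle_anova_two_groups(c(1, 2, 3), c(2, 3, 4))
  expect_equal(gc$statistic, 1.5, tolerance = 1e-12)
  expect_equal(gc$p.value, orc$p, tolerance = 1e-12)
  expect_equal(gc$difference, -1)
  expect_true(gc$conf.low <= gc$difference && gc$difference <= gc$conf.high)
})

test_that("identical groups give zero difference, F = 0, p = 1", {
  tb <- tibble::tibble(y = rep(c(5, 6, 7), 2), g = rep(0:1, each = 3))
  gc <- group_compare(tb, y, g)
  expect_equal(gc$difference, 0)
  expect_equal(gc$statistic, 0)
  expect_equal(gc$p.value, 1)
})

test_that("ANOVA p equals the pooled two-sided t-test p (F = t^2) on random tables", {
  set.seed(11)
  for (i in 1:25) {
    n1 <- sample(3:20, 1); n2 <- sample(3:20, 1)
    y1 <- rnorm(n1, 0, 1); y2 <- rnorm(n2, 0.4, 1.3)
    tb <- tibble::tibble(y = c(y1, y2), g = rep(0:1, c(n1, n2)))
    gc <- group_compare(tb, y, g)
    tt <- t.test(y1, y2, var.equal = TRUE)
    expect_equal(gc$p.value, tt$p.value, tolerance = 1e-12)
    expect_equal(gc$statistic, unname(tt$statistic)^2, tolerance = 1e-9)
  }
})

test_that("group comparison handles missing data pairwise and enforces group sizes", {
  tb <- tibble::tibble(y = c(1, 2, NA, 4, 5, 6, 7),
                       g = c(0, 0, 0, NA, 1, 1, 1))
  gc <- group_compare(tb, y, g)
  expect_equal(gc$groups$n, c(2, 3))
  expect_error(group_compare(tibble::tibble(y = c(1, 2, 3), g = c(0, 1, 1)),
                             y, g), "at least 2")
  expect_error(group_compare(tb, y, "missing_col"), "not found")
})

test_that("tidy and glance expose the comparison as tibbles", {
  tb <- tibble::tibble(y = rnorm(10), g = rep(0:1, 5))
  gc <- group_compare(tb, y, g)
  td <- generics::tidy(gc)
  expect_equal(nrow(td), 2)
  gl <- generics::glance(gc)
  expect_equal(nrow(gl), 1)
  expect_named(gl, c("metric", "group", "n", "n1", "n2", "mean1", "mean2",
                     "estimate", "conf.low", "conf.high", "statistic",
                     "p.value"))
})

test_that("correlation matches hand computations and exact linear cases", {
  tb <- tibble::tibble(x = c(1, 2, 3, 4), y = c(2, 1, 4, 3))
  expect_equal(correlate(tb, x, y)$estimate, 0.6, tolerance = 1e-12)
  lin <- tibble::tibble(x = 1:10, y = 2 * (1:10) + 1, z = -(1:10))
  expect_equal(correlate(lin, x, y)$estimate, 1, tolerance = 1e-12)
  expect_equal(correlate(lin, x, z)$estimate, -1, tolerance = 1e-12)
  expect_error(correlate(tibble::tibble(x = c(1, 1, 1), y = 1:3), x, y),
               "Zero variance")
  expect_error(correlate(tibble::tibble(x = c(1, 2, NA), y = c(1, NA, 3)),
                         x, y), "3 complete pairs")
})

test_that("full-infiltration exclusion keeps the zero boundary and counts removals", {
  tb <- tibble::tibble(subject_id = letters[1:3],
                       imat_effect_size = c(0.5, -0.2, 0.0))
  expect_message(out <- exclude_full_infiltration(tb), "1 fully")
  expect_equal(out$imat_effect_size, c(0.5, 0.0))
  expect_equal(attr(out, "n_excluded"), 1L)
  # no negatives -> identity
  clean <- tibble::tibble(imat_effect_size = c(0.1, 0, 2))
  expect_equal(suppressMessages(exclude_full_infiltration(clean))$imat_effect_size,
               clean$imat_effect_size)
  # brute-force equivalence on random tables
  set.seed(3)
  for (i in 1:10) {
    x <- tibble::tibble(imat_effect_size = round(rnorm(20, 0.2, 0.5), 2))
    out <- suppressMessages(exclude_full_infiltration(x))
    expect_identical(out$imat_effect_size,
                     x$imat_effect_size[x$imat_effect_size >= 0])
  }
})

test_that("cohort summary satisfies the weighted-mean identity", {
  set.seed(5)
  tb <- tibble::tibble(
    pri_history = rep(c(0, 1), c(21, 22)),
    years_wheelchair = c(rnorm(21, 10.7, 9.3), rnorm(22, 19.6, 13.3)),
    spasms = rbinom(43, 1, 0.6))
  sm <- cohort_summary(tb)
  yr <- dplyr::filter(sm, variable == "years_wheelchair")
  overall <- yr$mean[yr$group == "all"]
  g0 <- yr[yr$group == "pri_history=0", ]; g1 <- yr[yr$group == "pri_history=1", ]
  expect_equal(overall, (g0$n * g0$mean + g1$n * g1$mean) / (g0$n + g1$n),
               tolerance = 1e-12)
  sp <- dplyr::filter(sm, variable == "spasms", group == "all")
  expect_equal(sum(sp$count), 43)
  expect_equal(sum(sp$pct), 100, tolerance = 1e-9)
})

test_that("single-subject summaries flag the undefined SD", {
  tb <- tibble::tibble(pri_history = 0, bmi = 22.5)
  sm <- cohort_summary(tb, continuous = "bmi", categorical = character(0))
  row <- dplyr::filter(sm, group == "all")
  expect_equal(row$mean, 22.5)
  expect_equal(row$median, 22.5)
  expect_true(is.na(row$sd))
})

test_that("CI coverage is ~95% across replicate synthetic cohorts", {
  true_diff <- 0.21 - 0.58
  hits <- vapply(1:500, function(s) {
    coh <- generate_cohort(seed = 10000 + s, render = FALSE)
    tb <- dplyr::mutate(coh$truth, subqf_effect_size = subqf_contrast)
    gc <- group_compare(tb, subqf_effect_size, pri_history)
    gc$conf.low <= true_diff && true_diff <= gc$conf.high
  }, logical(1))
  expect_lt(abs(mean(hits) - 0.95), 0.02)
})

test_that("type-I error is ~5% when both groups share one distribution", {
  gp <- default_group_params()
  gp$pri <- gp$no_pri
  rejections <- vapply(1:500, function(s) {
    coh <- generate_cohort(seed = 20000 + s, group_params = gp, render = FALSE)
    tb <- dplyr::mutate(coh$truth, subqf_effect_size = subqf_contrast)
    group_compare(tb, subqf_effect_size, pri_history)$p.value < 0.05
  }, logical(1))
  expect_lt(abs(mean(rejections) - 0.05), 0.025)
})
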