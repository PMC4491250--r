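# independent order-statistic interpolation (coded from the h = (n-1)p + 1
# definition, not via stats::quantile)
oracle_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  vapply(p / 100, function(q) {
    h <- (n - 1) * q + 1
    lo <- floor(h)
    if (lo >= n) x[n] else x[lo] + (h - lo) * (x[lo + 1] - x[lo])
  }, numeric(1))
}

make_week_records <- function(weights_by_week) {
  do.call(rbind, lapply(names(weights_by_week), function(w) {
    data.frame(resolved_weeks = as.integer(w),
               birthweight_g = weights_by_week[[w]])
  }))
}

test_that("weekly empirical quantiles equal an independent sort-based oracle", {
  set.seed(91)
  recs <- make_week_records(list(
    `28` = round(rnorm(60, 1200, 180)),
    `33` = round(rlnorm(45, log(2000), 0.15)),
    `37` = round(runif(120, 2000, 3500))
  ))
  p <- c(3, 10, 25, 50, 75, 90, 97)
  tab <- empirical_percentiles(recs, percentiles = p, min_n = 20)
  expect_identical(tab$source, "empirical")
  expect_equal(tab$ga_weeks, c(28.5, 33.5, 37.5))
  for (i in seq_along(tab$ga_weeks)) {
    wk <- floor(tab$ga_weeks[i])
    expect_equal(unname(tab$weights[i, ]),
                 oracle_quantile(recs$birthweight_g[recs$resolved_weeks == wk], p))
  }
})

test_that("a constant week collapses every percentile to that value", {
  recs <- make_week_records(list(`30` = rep(1500, 25)))
  tab <- empirical_percentiles(recs, percentiles = c(10, 50, 90), min_n = 20)
  expect_true(all(tab$weights == 1500))
})

test_that("empirical quantiles are equivariant under positive affine rescaling", {
  set.seed(17)
  w <- round(rnorm(80, 2400, 300))
  a <- 1.3; b <- 120
  t1 <- empirical_percentiles(make_week_records(list(`35` = w)))
  t2 <- empirical_percentiles(make_week_records(list(`35` = a * w + b)))
  expect_equal(t2$weights, a * t1$weights + b)
})

test_that("thin weeks are omitted with a warning; an empty result errors", {
  recs <- make_week_records(list(`30` = rep(1500, 25), `31` = rep(1600, 5)))
  expect_warning(tab <- empirical_percentiles(recs, min_n = 20), "31")
  expect_equal(tab$ga_weeks, 30.5)
  expect_error(
    suppressWarnings(empirical_percentiles(recs, min_n = 200)),
    "no gestational week")
})

test_that("table comparison is zero on self and exact on a constructed scaling", {
  tab <- build_table(twin_standard_for_race("white"),
                     percentiles = c(10, 50, 90))
  self <- compare_tables(tab, tab)
  expect_true(all(self$per_percentile$mean_abs_dev_pct == 0))
  expect_true(all(self$per_percentile$max_abs_dev_pct == 0))
  scaled <- percentile_table(tab$ga_weeks, tab$percentiles, 1.10 * tab$weights,
                             source = "model", label = "scaled")
  cmp <- compare_tables(tab, scaled)
  expect_equal(cmp$per_percentile$mean_abs_dev_pct, rep(10, 3), tolerance = 1e-12)
  expect_equal(cmp$per_percentile$max_abs_dev_pct, rep(10, 3), tolerance = 1e-12)
})

test_that("comparison aligns by completed week and restricts to the overlap", {
  std <- twin_standard_for_race("white")
  model_mid <- build_table(std, ga_grid = seq(26.5, 36.5, 1),
                           percentiles = c(10, 50, 90))
  model_whole <- build_table(std, ga_grid = 30:38, percentiles = c(5, 50, 95))
  cmp <- compare_tables(model_mid, model_whole)
  expect_equal(cmp$ga_weeks, 30:36)
  expect_equal(cmp$per_percentile$percentile, 50)
  disjoint <- build_table(std, ga_grid = 24:25, percentiles = c(10, 50, 90))
  late <- build_table(std, ga_grid = 30:38, percentiles = c(10, 50, 90))
  expect_error(compare_tables(disjoint, late), "not comparable")
})

test_that("an empirical table from a model-generated cohort deviates below 1% at the median", {
  cfg <- clean_config(n = 30000, seed = 23)
  reg <- simulate_registry(cfg)
  emp <- empirical_percentiles(reg, percentiles = c(10, 50, 90))
  mod <- build_table(twin_standard(2727, 374), ga_grid = seq(24.5, 38.5, 1),
                     percentiles = c(10, 50, 90))
  cmp <- compare_tables(emp, mod)
  expect_lt(cmp$per_percentile$mean_abs_dev_pct[cmp$per_percentile$percentile == 50], 1)
})

test_that("injected LMP dating error widens the early 10th-90th band", {
  band_width <- function(ga_error, seed) {
    reg <- simulate_registry(clean_config(n = 40000, seed = seed,
                                          ga_error = ga_error))
    emp <- empirical_percentiles(reg, percentiles = c(10, 90),
                                 ga_range = c(24, 28), week_col = "lmp_weeks")
    sum(emp$weights[, 2] - emp$weights[, 1])
  }
  expect_gt(band_width(0.35, 61), band_width(0, 61))
})

test_that("comparison summaries serialise to JSON", {
  tab <- build_table(twin_standard(2600, 360), percentiles = c(10, 50, 90))
  path <- withr::local_tempfile(fileext = ".json")
  write_comparison(compare_tables(tab, tab), path)
  parsed <- jsonlite::fromJSON(path)
  expect_equal(parsed$per_percentile$percentile, c(10, 50, 90))
  expect_true(all(parsed$per_percentile$mean_abs_dev_pct == 0))
})
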