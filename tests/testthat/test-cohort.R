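test_that("the low-risk cascade retains compliant records and attributes exclusions", {
  good <- compliant_registry(70)
  bad <- rbind(
    compliant_registry(3, lmp_weeks = 12, ce_weeks = 12),   # unreliable GA
    compliant_registry(2, birthweight_g = 100),             # implausible weight
    compliant_registry(5, maternal_age_y = 36),
    compliant_registry(5, education = "lt_highschool"),
    compliant_registry(5, smoker = TRUE),
    compliant_registry(4, hypertensive_disorder = TRUE),
    compliant_registry(3, diabetes = TRUE),
    compliant_registry(3, prenatal_care_trimester = "later")
  )
  bad$id <- sprintf("b%03d", seq_len(nrow(bad)))
  lr <- low_risk_filter(rbind(good, bad))
  expect_equal(nrow(lr$records), 70)
  expect_equal(lr$report$excluded,
               c(3, 2, 5, 5, 5, 4, 3, 3))
  expect_equal(lr$report$excluded_missing, rep(0L, 8))
  expect_equal(lr$report$input[1], 100)
  expect_equal(lr$report$retained[8], 70)
  # internal bookkeeping: input - exclusions = retained at every step
  with(lr$report, expect_equal(input - excluded - excluded_missing, retained))
})

test_that("missing covariates exclude conservatively and are reported separately", {
  reg <- rbind(compliant_registry(5),
               compliant_record(id = "m1", smoker = NA),
               compliant_record(id = "m2", maternal_age_y = NA))
  lr <- low_risk_filter(reg)
  expect_equal(nrow(lr$records), 5)
  rep <- lr$report
  expect_equal(rep$excluded_missing[rep$step == "smoking"], 1)
  expect_equal(rep$excluded_missing[rep$step == "maternal_age"], 1)
  expect_equal(sum(rep$excluded), 0)
})

test_that("the retained set is criterion-order independent", {
  set.seed(12)
  reg <- simulate_registry(sim_config(n = 1500, seed = 12))
  lr <- low_risk_filter(reg)
  rec <- lr$records
  # independent conjunction of all criteria, no cascade
  ga <- reconcile_ga(reg$lmp_weeks, reg$ce_weeks, on_unresolved = "na")
  keep <- !is.na(ga$resolved_weeks) & ga$resolved_weeks >= 17 &
    ga$resolved_weeks <= 47 &
    !is.na(reg$birthweight_g) & reg$birthweight_g >= 250 &
    reg$birthweight_g <= 6000 &
    !is.na(reg$maternal_age_y) & reg$maternal_age_y >= 20 &
    reg$maternal_age_y <= 35 &
    reg$education %in% "highschool_plus" &
    reg$smoker %in% FALSE &
    reg$hypertensive_disorder %in% FALSE &
    reg$diabetes %in% FALSE &
    reg$prenatal_care_trimester %in% "first"
  expect_setequal(rec$id, reg$id[keep])
})

test_that("empty input yields an empty cohort with a zeroed report", {
  lr <- low_risk_filter(compliant_registry(1)[0, ])
  expect_equal(nrow(lr$records), 0)
  expect_true(all(lr$report$excluded == 0))
  expect_true(all(lr$report$retained == 0))
})

test_that("anchor estimation matches a brute-force mean/SD oracle", {
  set.seed(31)
  w <- round(rnorm(57, 2650, 380))
  reg <- compliant_registry(57, birthweight_g = 1)
  reg$birthweight_g <- w
  reg$resolved_weeks <- 37L
  est <- estimate_anchor(reg)
  m_oracle <- sum(w) / length(w)
  sd_oracle <- sqrt(sum((w - m_oracle)^2) / (length(w) - 1))
  expect_equal(est$mean_g, m_oracle)
  expect_equal(est$sd_g, sd_oracle)
  expect_equal(est$n, 57L)
  expect_equal(est$cv_pct, 100 * sd_oracle / m_oracle)
})

test_that("thin and degenerate anchor strata are flagged", {
  reg <- compliant_registry(2, birthweight_g = 2500)
  reg$resolved_weeks <- 37L
  expect_warning(est <- estimate_anchor(reg), "degenerate")
  expect_true(est$degenerate)
  expect_equal(est$sd_g, 0)
  one <- reg[1, ]
  expect_error(estimate_anchor(one), "insufficient stratum.*37")
  expect_error(estimate_anchor(reg, completed_week = 30), "30")
})

test_that("race anchors report cohort shares and omit unestimable strata", {
  reg <- compliant_registry(10)
  reg$birthweight_g <- seq(2500, 2950, by = 50)
  reg$resolved_weeks <- 37L
  single <- anchor_by_race(reg)
  expect_equal(nrow(single), 1)
  expect_equal(single$share_pct, 100)
  two <- rbind(reg, transform(reg, race = "black", id = paste0("x", id)))
  res <- anchor_by_race(two)
  expect_equal(sort(res$share_pct), c(50, 50))
  mixed <- rbind(compliant_registry(10),
                 compliant_record(id = "solo", race = "asian"))
  mixed$birthweight_g <- c(seq(2500, 2950, by = 50), 2600)
  mixed$resolved_weeks <- 37L
  expect_warning(res2 <- anchor_by_race(mixed), "asian")
  expect_true(is.na(res2$mean_g[res2$race == "asian"]))
  expect_equal(res2$n[res2$race == "asian"], 1)
})

test_that("a synthetic week-37 cohort recovers its generating anchor within 3 SE", {
  cfg <- clean_config(n = 2000, seed = 55, mean_g = 2605, sd_g = 378,
                      weeks = 37)
  reg <- simulate_registry(cfg)
  lr <- low_risk_filter(reg)
  est <- estimate_anchor(lr$records)
  se <- 378 / sqrt(est$n)
  expect_lt(abs(est$mean_g - 2605), 3 * se)
  # closing the loop: re-anchor a new cohort from the estimate
  std <- twin_standard(est$mean_g, est$sd_g)
  cfg2 <- clean_config(n = 2000, seed = 56, mean_g = est$mean_g,
                       sd_g = est$sd_g, weeks = 37)
  est2 <- estimate_anchor(low_risk_filter(simulate_registry(cfg2))$records)
  expect_lt(abs(est2$mean_g - est$mean_g), 3 * est$sd_g / sqrt(est2$n))
  expect_lt(abs(adjusted_median(std, 37.5) - est$mean_g), 0.5)
})
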