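test_that("Kruskal-Wallis matches the brute-force rank oracle", {
  g <- list(c(1, 2, 3), c(4, 5, 6))
  r <- kruskal_wallis(g)
  expect_equal(r$H, kw_oracle(g))
  expect_equal(r$H, 27 / 7, tolerance = 1e-12)  # 3.857

  # random small groups, with and without ties, up to 10 elements
  set.seed(3)
  for (i in 1:20) {
    k <- sample(2:4, 1)
    groups <- lapply(seq_len(k), function(j)
      sample(1:6, sample(2:10, 1), replace = TRUE))  # replacement forces ties
    r <- kruskal_wallis(groups)
    expect_equal(r$H, kw_oracle(groups), tolerance = 1e-12)
    expect_equal(r$p_value,
                 stats::pchisq(r$H, k - 1, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("identical groups give H = 0 and p = 1", {
  r <- kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(r$H, 0)
  expect_equal(r$p_value, 1)
})

test_that("H is invariant under strictly monotone transforms", {
  set.seed(9)
  groups <- list(rnorm(8, 10), rnorm(9, 11), rnorm(6, 10.5))
  h0 <- kruskal_wallis(groups)$H
  expect_equal(kruskal_wallis(lapply(groups, exp))$H, h0)
  expect_equal(kruskal_wallis(lapply(groups, function(x) 3 * x - 100))$H, h0)
})

test_that("undersized groups are rejected", {
  expect_error(kruskal_wallis(list(1, c(2, 3))), "at least 2")
  expect_error(kruskal_wallis(list(c(1, 2))), "two groups")
})

test_that("analytical CV is the sample relative standard deviation", {
  expect_equal(analytical_cv(rep(30.5, 10)), 0)
  expect_equal(analytical_cv(c(10, 12)), sqrt(2) / 11 * 100)
  expect_equal(analytical_cv(c(10, 12)), 12.8565, tolerance = 1e-4)
  expect_error(analytical_cv(5), "at least 2")
  expect_error(analytical_cv(c(-1, 1)), "zero")
})

test_that("zero-effect trials give a zero estimate and non-positive bound", {
  t0 <- zero_effect_table()
  r <- annual_increase_lower_bound(t0, seed = 5)
  expect_equal(r$estimate_tc_ha_yr, 0)
  expect_lte(r$lower_bound_tc_ha_yr, 0)
  r_exp <- annual_increase_lower_bound(t0, method = "exp_only", seed = 5)
  expect_equal(r_exp$estimate_tc_ha_yr, 0)
})

test_that("the bootstrap bound is seed-reproducible and below the estimate", {
  cores <- simulate_trial(trial_params(), seed = 21)
  a <- annual_increase_lower_bound(cores, seed = 99, resamples = 2000)
  b <- annual_increase_lower_bound(cores, seed = 99, resamples = 2000)
  expect_identical(a, b)
  expect_lt(a$lower_bound_tc_ha_yr, a$estimate_tc_ha_yr)
  # DiD and EXP-only agree in expectation but differ per sample
  e <- annual_increase_lower_bound(cores, method = "exp_only", seed = 99)
  expect_false(isTRUE(all.equal(a$estimate_tc_ha_yr, e$estimate_tc_ha_yr)))
  # bound requires a seed; the t-based alternative does not
  expect_error(annual_increase_lower_bound(cores), "seed")
  tb <- annual_increase_lower_bound(cores, bound = "t")
  expect_lt(tb$lower_bound_tc_ha_yr, tb$estimate_tc_ha_yr)
})

test_that("the DiD point estimate is the four-mean contrast over the interval", {
  cores <- simulate_trial(trial_params(), seed = 8)
  m <- with(cores, tapply(soc_stock_tc_ha, paste(site, time), mean))
  expect_equal(
    annual_increase_lower_bound(cores, bound = "t")$estimate_tc_ha_yr,
    (m[["EXP T1"]] - m[["EXP T0"]]) - (m[["CTRL T1"]] - m[["CTRL T0"]]))
  # a two-year interval halves the annualised estimate
  expect_equal(
    annual_increase_lower_bound(cores, bound = "t",
                                interval_years = 2)$estimate_tc_ha_yr,
    annual_increase_lower_bound(cores, bound = "t")$estimate_tc_ha_yr / 2)
})

test_that("missing strata are a hard error", {
  cores <- simulate_trial(trial_params(), seed = 3)
  no_ctrl <- soil_sample_table(as.data.frame(cores[cores$site == "EXP", ]))
  expect_error(annual_increase_lower_bound(no_ctrl, seed = 1), "CTRL")
  # but EXP-only analysis still works
  r <- annual_increase_lower_bound(no_ctrl, method = "exp_only", seed = 1)
  expect_true(is.finite(r$lower_bound_tc_ha_yr))
})

test_that("relative increase is the delta over the baseline stock", {
  expect_equal(relative_increase(0, 30), 0)
  expect_equal(relative_increase(1.2, 30), 4.0)
  expect_equal(relative_increase(1.34, 1.34 / 0.044), 4.4)
  expect_error(relative_increase(1, 0), "positive")
})

test_that("analyze_trial bundles the test, bound and relative increase", {
  cores <- simulate_trial(trial_params(), seed = 14)
  r <- analyze_trial(cores, seed = 15, resamples = 2000)
  expect_s3_class(r, "trial_result")
  expect_gte(r$p_value, 0)
  expect_lte(r$p_value, 1)
  expect_lte(r$lower_bound, r$annual_delta_mean)
  expect_equal(r$relative_increase_pct,
               relative_increase(r$annual_delta_mean,
                                 mean(cores$soc_stock_tc_ha[
                                   cores$site == "EXP" & cores$time == "T0"])))
})
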