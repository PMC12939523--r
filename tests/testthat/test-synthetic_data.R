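test_that("trial simulation is deterministic under a fixed seed", {
  a <- simulate_trial(trial_params(), seed = 17)
  b <- simulate_trial(trial_params(), seed = 17)
  expect_identical(a, b)
  c <- simulate_trial(trial_params(), seed = 18)
  expect_false(identical(a$soc_stock_tc_ha, c$soc_stock_tc_ha))
  expect_equal(attr(a, "rng_kind"), RNGkind()[1])
})

test_that("generated tables satisfy the sample-table design", {
  t <- simulate_trial(trial_params(), seed = 1)
  expect_s3_class(t, "soil_sample_table")
  counts <- table(t$site, t$time)
  expect_equal(counts["EXP", "T0"], 9)
  expect_equal(counts["CTRL", "T0"], 6)
  expect_equal(counts["EXP", "T1"], 9)
  expect_equal(counts["CTRL", "T1"], 9)
  expect_true(all(t$soc_stock_tc_ha > 0))
  expect_false(anyDuplicated(t$sample_id) > 0)
  # coordinates stay within ~a site's footprint of the center
  expect_true(all(abs(t$lat - 64.0717) < 0.01))
  expect_error(simulate_trial(trial_params(n_ctrl_t0 = 1), seed = 1),
               ">= 2")
  expect_error(simulate_trial(trial_params()), "seed")
})

test_that("between-core variability is recovered at the configured CV", {
  p <- trial_params()
  cvs <- vapply(1:200, function(s) {
    x <- simulate_trial(p, seed = s)
    v <- x$soc_stock_tc_ha[x$site == "EXP" & x$time == "T0"]
    stats::sd(v) / mean(v)
  }, numeric(1))
  # total CV combines between-core (0.12) and analytical (0.0344) noise
  target <- sqrt(0.12^2 + 0.0344^2 + (0.12 * 0.0344)^2)
  expect_lt(abs(mean(cvs) - target) / target, 0.15)
})

test_that("the generator recovers the treatment effect in expectation", {
  p <- trial_params()
  est <- vapply(1:2000, function(s) {
    x <- simulate_trial(p, seed = s)
    mean(x$soc_stock_tc_ha[x$site == "EXP" & x$time == "T1"]) -
      mean(x$soc_stock_tc_ha[x$site == "EXP" & x$time == "T0"])
  }, numeric(1))
  expect_lt(abs(mean(est) - 1.6), 0.1)
  # control site drifts around zero
  ctrl <- vapply(1:500, function(s) {
    x <- simulate_trial(p, seed = s)
    mean(x$soc_stock_tc_ha[x$site == "CTRL" & x$time == "T1"]) -
      mean(x$soc_stock_tc_ha[x$site == "CTRL" & x$time == "T0"])
  }, numeric(1))
  expect_lt(abs(mean(ctrl)), 0.3)
})

test_that("paired mode reuses baseline core deviates", {
  p <- trial_params(between_core_cv = 0.2, analytical_cv = 0, paired = TRUE)
  t <- simulate_trial(p, seed = 4)
  exp0 <- t$soc_stock_tc_ha[t$site == "EXP" & t$time == "T0"]
  exp1 <- t$soc_stock_tc_ha[t$site == "EXP" & t$time == "T1"]
  # identical relative deviates: T1/T0 is the constant mean ratio
  expect_equal(exp1 / exp0, rep(32.1 / 30.5, 9), tolerance = 1e-12)
})

test_that("replicate simulation matches the assay-noise model", {
  r <- simulate_replicates(cv = 0, seed = 2)
  expect_equal(r, rep(30.5, 10))
  expect_length(simulate_replicates(n = 2, seed = 2), 2)
  expect_identical(simulate_replicates(seed = 6), simulate_replicates(seed = 6))
  expect_error(simulate_replicates(n = 1, seed = 1), ">= 2")
})

test_that("analytical CV is recovered from simulated replicates", {
  cvs <- vapply(1:2000, function(s) analytical_cv(simulate_replicates(seed = s)),
                numeric(1))
  expect_lt(abs(mean(cvs) - 3.44), 0.2)
})

test_that("fixture writing is byte-stable and round-trips the config", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- make_fixtures(d1)
  p2 <- make_fixtures(d2)
  expect_identical(lapply(p1, readLines), lapply(p2, readLines))
  inv <- read_inventory(file.path(d1, "inventory_table1.csv"))
  expect_equal(nrow(inv), 26)
  expect_true(any(inv$flow_name == "CO_2" & inv$amount == 1.60248 &
                    inv$unit == "t" & inv$direction_sign == -1L))
  cfg <- read_config(file.path(d1, "default_config.yaml"))
  expect_equal(cfg$sequestration$r_soc, default_config()$sequestration$r_soc)
  expect_equal(cfg$stages$sequestration_kg_per_cu, 1602.48)
})
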