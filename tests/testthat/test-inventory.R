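test_that("shipped inventory fixture reads with the documented structure", {
  inv <- read_inventory(phyco_extdata("inventory_table1.csv"))
  expect_s3_class(inv, "inventory_table")
  expect_equal(nrow(inv), 26)
  seq_row <- inv[inv$comment == "Carbon sequestration", ]
  expect_equal(seq_row$flow_name, "CO_2")
  expect_equal(seq_row$amount, 1.60248)
  expect_equal(seq_row$unit, "t")
  expect_equal(seq_row$compartment, "elementary")
  expect_equal(seq_row$direction_sign, -1L)
  # both elementary CO2 rows are removals
  co2 <- inv[inv$flow_name == "CO_2", ]
  expect_equal(co2$direction_sign, c(-1L, -1L))
})

test_that("inventory reading handles degenerate and invalid files", {
  hdr <- "flow_name,amount,unit,compartment,direction_sign"
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(hdr, f)
  empty <- read_inventory(f)
  expect_equal(nrow(empty), 0)

  writeLines(c(hdr, "Steel,1.5,lbs,technosphere,1"), f)
  expect_error(read_inventory(f), "lbs")
  expect_error(read_inventory(f), "rows 1")

  writeLines(c(hdr, "CO_2,-2,kg,elementary,1"), f)
  expect_error(read_inventory(f), "direction_sign")

  expect_error(read_inventory("no/such/file.csv"), "not found")
})

test_that("characterization is a signed linear map in SI units", {
  cf <- cf_table("CO_2", "climate_GWP100", 1.0)
  one <- inventory_table("CO_2", 2, "kg", "elementary", 1L)
  expect_equal(characterize(one, cf)$totals[["climate_GWP100"]], 2.0)

  seq_flow <- inventory_table("CO_2", 1.60248, "t", "elementary", -1L)
  expect_equal(characterize(seq_flow, cf)$totals[["climate_GWP100"]], -1602.48)

  grams <- inventory_table("CO_2", 500, "g", "elementary", 1L)
  expect_equal(characterize(grams, cf)$totals[["climate_GWP100"]], 0.5)
})

test_that("missing factors error loudly, never silently zero", {
  cf <- cf_table("CO_2", "climate_GWP100", 1.0)
  inv <- inventory_table(c("CO_2", "N2O"), c(1, 1), "kg", "elementary",
                         c(1L, 1L))
  expect_error(characterize(inv, cf), "N2O")
  # explicit ignore set allows the gap
  ok <- characterize(inv, cf, ignore = "N2O")
  expect_equal(ok$totals[["climate_GWP100"]], 1.0)
  # technosphere flows without factors are skipped but recorded
  mix <- inventory_table(c("CO_2", "Steel"), c(1, 1), "kg",
                         c("elementary", "technosphere"), c(1L, 1L))
  res <- characterize(mix, cf)
  expect_equal(res$uncharacterized, "Steel")
})

test_that("characterization is linear and additive over random inventories", {
  set.seed(42)
  for (i in 1:8) {
    fx <- random_inventory()
    base <- characterize(fx$inv, fx$cf)$totals
    k <- stats::runif(1, 0.2, 5)
    scaled <- characterize(scale_inventory(fx$inv, k), fx$cf)$totals
    expect_equal(scaled, k * base, tolerance = 1e-12)

    fy <- random_inventory()
    fy$inv$flow_name <- paste0("y_", fy$inv$flow_name)
    fy$cf$flow_name <- paste0("y_", fy$cf$flow_name)
    cf_union <- cf_table(c(fx$cf$flow_name, fy$cf$flow_name),
                         "climate_GWP100", c(fx$cf$factor, fy$cf$factor))
    both <- rbind(as.data.frame(fx$inv), as.data.frame(fy$inv))
    both <- inventory_table(both$flow_name, both$amount, both$unit,
                            both$compartment, both$direction_sign, both$stage)
    expect_equal(characterize(both, cf_union)$totals[["climate_GWP100"]],
                 characterize(fx$inv, fx$cf)$totals[["climate_GWP100"]] +
                   characterize(fy$inv, fy$cf)$totals[["climate_GWP100"]],
                 tolerance = 1e-12)
  }
})

test_that("direction-signed CO2 flows reproduce the net biogenic balance", {
  inv <- read_inventory(phyco_extdata("inventory_table1.csv"))
  res <- characterize(inv, gwp_factor_table(), ignore = "Land occupation")
  # biofixation (-0.40179 kg) plus sequestration (-1602.48 kg)
  expect_equal(res$totals[["climate_GWP100"]], -(0.40179 + 1602.48))
})

test_that("stage breakdown partitions the total", {
  set.seed(7)
  for (i in 1:5) {
    fx <- random_inventory()
    res <- stage_totals(fx$inv, fx$cf)
    expect_equal(sum(res$breakdown[, "climate_GWP100"]),
                 characterize(fx$inv, fx$cf)$totals[["climate_GWP100"]],
                 tolerance = 1e-12)
  }
  # a single stage collapses breakdown onto the total
  one <- inventory_table("CO_2", 3, "kg", "elementary", 1L, stage = "only")
  res <- stage_totals(one, cf_table("CO_2", "climate_GWP100", 1))
  expect_equal(unname(res$breakdown["only", "climate_GWP100"]),
               res$totals[["climate_GWP100"]])
  # unmapped flows are an error
  bare <- inventory_table("CO_2", 3, "kg", "elementary", 1L)
  expect_error(stage_totals(bare, cf_table("CO_2", "climate_GWP100", 1)),
               "stage label")
})
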