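# Shared helpers: independent oracles and small fixture builders.

# Brute-force Kruskal-Wallis H with tie correction, straight from the
# rank-sum definition; independent of stats::kruskal.test.
kw_oracle <- function(groups) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  n <- length(x)
  r <- rank(x)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, sum)^2 / lengths(groups)) - 3 * (n + 1)
  ties <- table(x)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# Random small inventory table (technosphere + elementary CO_2 rows) with a
# matching factor table; used for linearity/additivity properties.
random_inventory <- function(n = 6) {
  flows <- paste0("flow_", seq_len(n))
  inv <- inventory_table(
    flow_name = c(flows, "CO_2"),
    amount = round(stats::runif(n + 1, 0.1, 10), 4),
    unit = sample(c("kg", "t", "g", "MJ"), n + 1, replace = TRUE),
    compartment = c(rep("technosphere", n), "elementary"),
    direction_sign = c(sample(c(1L, 1L, -1L), n, replace = TRUE), -1L),
    stage = sample(c("a", "b", "c"), n + 1, replace = TRUE))
  cf <- cf_table(c(flows, "CO_2"), "climate_GWP100",
                 round(stats::runif(n + 1, 0.1, 5), 4))
  list(inv = inv, cf = cf)
}

scale_inventory <- function(inv, k) {
  inv$amount <- inv$amount * k
  validate_inv <- phycocarbon::inventory_table
  validate_inv(inv$flow_name, inv$amount, inv$unit, inv$compartment,
               inv$direction_sign, inv$stage)
}

# Zero-effect soil table where T1 repeats T0 exactly on both sites.
zero_effect_table <- function(exp0 = c(29, 31, 30, 32, 28.5),
                              ctrl0 = c(30, 29.5, 31, 30.5)) {
  soil_sample_table(data.frame(
    site = rep(c("EXP", "CTRL"), times = c(2 * length(exp0), 2 * length(ctrl0))),
    time = c(rep(c("T0", "T1"), each = length(exp0)),
             rep(c("T0", "T1"), each = length(ctrl0))),
    soc_stock_tc_ha = c(exp0, exp0, ctrl0, ctrl0),
    stringsAsFactors = FALSE))
}
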