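## Seeded synthetic field-trial generator.
##
## Emulates the Olfus two-site trial design: two 12.45 ha sites (treated EXP,
## untreated CTRL), 60 cm cores, 9 EXP / 6 CTRL cores at baseline T0 and
## 9 / 9 one year later at T1. Between-core variation is lognormal (SOC
## stocks are positive and right-skewed); analytical noise is multiplicative
## at the stated assay CV. Cores are destructive samples taken at new
## positions, so T0 and T1 draws are independent by default; `paired = TRUE`
## reuses the T0 between-core deviates at T1 for method testing.

#' Parameters of the synthetic soil-core trial
#'
#' @param baseline_stock_mean mean SOC stock at T0, tC/ha to 60 cm
#'   (default 30.5, the stock implied by a 1.34 tC/ha/yr change being a 4.4%
#'   relative increase).
#' @param between_core_cv between-core coefficient of variation
#'   (default 0.12; the real sites' spatial variability is unpublished, so
#'   this is an assumption and deliberately prominent).
#' @param analytical_cv multiplicative assay CV (default 0.0344).
#' @param annual_effect_exp treatment-driven annual SOC stock increase on
#'   EXP, tC/ha/yr (default 1.6).
#' @param annual_effect_ctrl annual change on CTRL (default 0).
#' @param n_exp_t0,n_ctrl_t0,n_exp_t1,n_ctrl_t1 core counts per stratum
#'   (defaults 9, 6, 9, 9).
#' @param site_center_lat,site_center_lon site coordinates (defaults
#'   64.0717 N, -21.4831 E).
#' @param paired reuse T0 between-core deviates at T1 (default FALSE).
#' @return List of class `"trial_params"`.
#' @export
trial_params <- function(baseline_stock_mean = 30.5, between_core_cv = 0.12,
                         analytical_cv = 0.0344, annual_effect_exp = 1.6,
                         annual_effect_ctrl = 0.0,
                         n_exp_t0 = 9, n_ctrl_t0 = 6,
                         n_exp_t1 = 9, n_ctrl_t1 = 9,
                         site_center_lat = 64.0717,
                         site_center_lon = -21.4831,
                         paired = FALSE) {
  counts <- c(n_exp_t0, n_ctrl_t0, n_exp_t1, n_ctrl_t1)
  if (any(counts < 2)) stop("all stratum counts must be >= 2", call. = FALSE)
  stopifnot(between_core_cv >= 0, analytical_cv >= 0, baseline_stock_mean > 0)
  structure(list(baseline_stock_mean = baseline_stock_mean,
                 between_core_cv = between_core_cv,
                 analytical_cv = analytical_cv,
                 annual_effect_exp = annual_effect_exp,
                 annual_effect_ctrl = annual_effect_ctrl,
                 n_exp_t0 = n_exp_t0, n_ctrl_t0 = n_ctrl_t0,
                 n_exp_t1 = n_exp_t1, n_ctrl_t1 = n_ctrl_t1,
                 site_center_lat = site_center_lat,
                 site_center_lon = site_center_lon,
                 paired = paired),
            class = "trial_params")
}

## lognormal deviates with a given arithmetic mean and CV; cv = 0 degenerates
## to the constant mean
.rlnorm_mean_cv <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate a soil-core trial table
#'
#' Per-core stock = lognormal(stratum mean, between-core CV) x multiplicative
#' lognormal analytical noise (unit mean, assay CV). EXP-T1 stratum mean is
#' `baseline + annual_effect_exp`; CTRL-T1 is `baseline +
#' annual_effect_ctrl`. Coordinates are jittered uniformly within roughly a
#' 12.45 ha square around each site center (CTRL offset east). Identical
#' seeds give identical tables.
#'
#' @param p a [trial_params()] object.
#' @param seed integer RNG seed (required).
#' @return A [soil_sample_table()] with columns
#'   `site, time, sample_id, soc_stock_tc_ha, lat, lon`.
#' @export
simulate_trial <- function(p = trial_params(), seed) {
  stopifnot(inherits(p, "trial_params"))
  if (missing(seed) || is.null(seed)) stop("a seed is required", call. = FALSE)
  set.seed(as.integer(seed))
  strata <- list(
    list(site = "EXP",  time = "T0", n = p$n_exp_t0,
         mean = p$baseline_stock_mean),
    list(site = "CTRL", time = "T0", n = p$n_ctrl_t0,
         mean = p$baseline_stock_mean),
    list(site = "EXP",  time = "T1", n = p$n_exp_t1,
         mean = p$baseline_stock_mean + p$annual_effect_exp),
    list(site = "CTRL", time = "T1", n = p$n_ctrl_t1,
         mean = p$baseline_stock_mean + p$annual_effect_ctrl))
  half_side <- sqrt(12.45 * 1e4) / 2                     # m, ~12.45 ha square
  lat_j <- half_side / 111320                            # deg per m latitude
  lon_j <- half_side / (111320 * cos(p$site_center_lat * pi / 180))
  paired_dev <- list()
  rows <- lapply(strata, function(s) {
    key <- s$site
    if (p$paired && s$time == "T1" && !is.null(paired_dev[[key]]) &&
        length(paired_dev[[key]]) == s$n) {
      core <- paired_dev[[key]] * s$mean
    } else {
      core <- .rlnorm_mean_cv(s$n, s$mean, p$between_core_cv)
      if (p$paired && s$time == "T0") paired_dev[[key]] <<- core / s$mean
    }
    stock <- core * .rlnorm_mean_cv(s$n, 1, p$analytical_cv)
    lon0 <- p$site_center_lon + if (s$site == "CTRL") 3 * lon_j else 0
    data.frame(site = s$site, time = s$time,
               sample_id = paste(s$site, s$time, seq_len(s$n), sep = "-"),
               soc_stock_tc_ha = stock,
               lat = p$site_center_lat + stats::runif(s$n, -lat_j, lat_j),
               lon = lon0 + stats::runif(s$n, -lon_j, lon_j),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "rng_kind") <- RNGkind()[1]
  soil_sample_table(out)
}

#' Simulate replicate measurements of one homogenised sample
#'
#' Multiplicative normal noise at the stated assay CV around the true value;
#' [analytical_cv()] recovers `cv` in expectation (up to the small-sample
#' bias of the sample SD).
#'
#' @param n number of replicates (>= 2, default 10).
#' @param cv assay coefficient of variation (default 0.0344).
#' @param mean true value of the sample (default 30.5).
#' @param seed integer RNG seed (required).
#' @return Numeric vector of length `n`.
#' @export
simulate_replicates <- function(n = 10, cv = 0.0344, mean = 30.5, seed) {
  if (n < 2) stop("need n >= 2 replicates", call. = FALSE)
  stopifnot(cv >= 0)
  if (missing(seed) || is.null(seed)) stop("a seed is required", call. = FALSE)
  set.seed(as.integer(seed))
  mean * (1 + stats::rnorm(n, 0, cv))
}
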