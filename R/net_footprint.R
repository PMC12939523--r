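## Net per-CU carbon footprint, one-at-a-time sensitivity and scenarios.
##
## The net footprint composes the stage emission intensities (cultivation +
## extraction, gross 4.98 kg CO2-eq/CU) with the buffered sequestration
## credit (1602.48 kg CO2-eq/CU), giving the baseline -1597.50 kg CO2-eq/CU.
## OAT responses for the non-sequestration parameters use per-parameter GWP
## contributions back-solved from the published sensitivity table; they are
## reconstructions, not measured stage data, and are plain config values.

#' Stage emission profile per color unit
#'
#' @param cultivation_kg_per_cu climate impact of cultivation, kg CO2-eq/CU
#'   (default 0.15).
#' @param extraction_kg_per_cu climate impact of extraction/drying, kg
#'   CO2-eq/CU (default 4.83).
#' @param biofixation_kg_per_cu CO2 taken up during cultivation, kg/CU,
#'   stored as a positive removal magnitude (default 0.40179). Already netted
#'   into the stage intensities; carried as metadata.
#' @param cultivation_kg_per_kg_wet cultivation intensity per kg wet biomass,
#'   metadata only (default 4.19; no wet-to-dry ratio is asserted that would
#'   reconcile it with the per-CU figure).
#' @param contributions named numeric vector of OAT parameter contributions
#'   in kg CO2-eq/CU per unit fractional change; defaults are back-solved
#'   reconstructions (`cultivation_energy` 5.15, `cultivation_yield` -5.60,
#'   `transport` 0.75).
#' @return List of class `"stage_profile"`.
#' @export
stage_profile <- function(cultivation_kg_per_cu = 0.15,
                          extraction_kg_per_cu = 4.83,
                          biofixation_kg_per_cu = 0.40179,
                          cultivation_kg_per_kg_wet = 4.19,
                          contributions = c(cultivation_energy = 5.15,
                                            cultivation_yield = -5.60,
                                            transport = 0.75)) {
  stopifnot(cultivation_kg_per_cu >= 0, extraction_kg_per_cu >= 0,
            biofixation_kg_per_cu >= 0)
  structure(list(cultivation_kg_per_cu = cultivation_kg_per_cu,
                 extraction_kg_per_cu = extraction_kg_per_cu,
                 biofixation_kg_per_cu = biofixation_kg_per_cu,
                 cultivation_kg_per_kg_wet = cultivation_kg_per_kg_wet,
                 contributions = contributions),
            class = "stage_profile")
}

#' Gross stage emissions per CU
#'
#' @param stages a [stage_profile()].
#' @return Cultivation plus extraction emissions, kg CO2-eq/CU.
#' @export
gross_emissions_per_cu <- function(stages = stage_profile()) {
  stages$cultivation_kg_per_cu + stages$extraction_kg_per_cu
}

#' Net GWP100 per color unit
#'
#' `(cultivation + extraction) - sequestration`; negative when the credit
#' dominates. Defaults reproduce the baseline -1597.50 kg CO2-eq/CU.
#'
#' @param stages a [stage_profile()].
#' @param seq_kg_per_cu sequestration credit, kg CO2-eq/CU, positive
#'   magnitude (default the canonical inventory flow 1602.48).
#' @return Net footprint in kg CO2-eq per CU.
#' @export
net_gwp_per_cu <- function(stages = stage_profile(),
                           seq_kg_per_cu = canonical_sequestration_kg_per_cu()) {
  stopifnot(is.finite(seq_kg_per_cu))
  gross_emissions_per_cu(stages) - seq_kg_per_cu
}

#' Percentage change against a baseline footprint
#'
#' `(value - baseline) / |baseline| * 100`: a more negative (more
#' carbon-negative) net prints as a negative percentage, matching the sign
#' convention of the sensitivity tables.
#'
#' @param value,baseline net footprints in kg CO2-eq/CU; `baseline != 0`.
#' @return Signed percentage change.
#' @export
pct_change_from_baseline <- function(value, baseline) {
  if (baseline == 0) stop("baseline must be nonzero", call. = FALSE)
  (value - baseline) / abs(baseline) * 100
}

#' One-at-a-time sensitivity analysis
#'
#' Each parameter is perturbed by the signed fractional `delta` with all
#' others fixed. `sequestration_rate` scales the credit term; any other id
#' must name an entry of the profile's `contributions`, whose response is
#' linear: `net(delta) = baseline + delta * contribution`.
#'
#' @param stages a [stage_profile()].
#' @param seq_kg_per_cu sequestration credit, kg CO2-eq/CU.
#' @param parameters parameter ids to perturb (default: sequestration rate
#'   plus every contribution entry).
#' @param deltas signed fractional perturbations, `|delta| < 1`
#'   (default `c(-0.2, 0.2)`).
#' @return `data.frame` with columns `parameter, delta, net_kg_per_cu,
#'   pct_change`.
#' @export
oat_sensitivity <- function(stages = stage_profile(),
                            seq_kg_per_cu = canonical_sequestration_kg_per_cu(),
                            parameters = c("sequestration_rate",
                                           names(stages$contributions)),
                            deltas = c(-0.2, 0.2)) {
  stopifnot(all(abs(deltas) < 1))
  baseline <- net_gwp_per_cu(stages, seq_kg_per_cu)
  grid <- expand.grid(parameter = parameters, delta = deltas,
                      stringsAsFactors = FALSE)
  grid <- grid[order(match(grid$parameter, parameters), grid$delta), ]
  net <- mapply(function(param, d) {
    if (param == "sequestration_rate") {
      gross_emissions_per_cu(stages) - (1 + d) * seq_kg_per_cu
    } else if (param %in% names(stages$contributions)) {
      baseline + d * stages$contributions[[param]]
    } else {
      stop("unknown sensitivity parameter: ", param, call. = FALSE)
    }
  }, grid$parameter, grid$delta)
  data.frame(parameter = grid$parameter, delta = grid$delta,
             net_kg_per_cu = unname(net),
             pct_change = pct_change_from_baseline(unname(net), baseline) ,
             row.names = NULL)
}

#' Scenario definitions
#'
#' The four named system-configuration scenarios:
#' * `S1_conservative_seq` — sequestration rate halved (`seq_factor` 0.5).
#' * `S2_optimized_cultivation` — cultivation energy use reduced 90%
#'   (removes `energy_reduction * cultivation_energy` contribution).
#' * `S3_ground_application` — drone spraying replaced by ground-based
#'   application; modelled as a net emission delta (default -1.60 kg/CU,
#'   a back-solved reconstruction).
#' * `S4_high_pc_content` — pigment yield raised to 20% of dry biomass; all
#'   per-CU flows (emissions and credit) scale by `y_base / y_new`.
#'
#' @param id one of the four scenario ids.
#' @param overrides named list overriding the scenario's own parameters
#'   (`seq_factor`, `energy_reduction`, `emission_delta_kg_per_cu`, `y_new`).
#' @return List of class `"scenario_spec"`.
#' @export
scenario_spec <- function(id = c("S1_conservative_seq",
                                 "S2_optimized_cultivation",
                                 "S3_ground_application",
                                 "S4_high_pc_content"),
                          overrides = list()) {
  id <- match.arg(id)
  defaults <- switch(id,
    S1_conservative_seq = list(seq_factor = 0.5),
    S2_optimized_cultivation = list(energy_reduction = 0.90),
    S3_ground_application = list(emission_delta_kg_per_cu = -1.60),
    S4_high_pc_content = list(y_new = 0.20))
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0) {
    stop("invalid override(s) for ", id, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  defaults[names(overrides)] <- overrides
  structure(list(id = id, params = defaults), class = "scenario_spec")
}

#' Run a configuration scenario
#'
#' @param s a [scenario_spec()].
#' @param stages a [stage_profile()].
#' @param seq_kg_per_cu baseline sequestration credit, kg CO2-eq/CU.
#' @param y_base baseline pigment yield fraction (used by the high-content
#'   scenario's biomass scaling law).
#' @return List with `id`, `net_kg_per_cu` and `pct_change` from baseline.
#' @export
run_scenario <- function(s, stages = stage_profile(),
                         seq_kg_per_cu = canonical_sequestration_kg_per_cu(),
                         y_base = 0.0322) {
  stopifnot(inherits(s, "scenario_spec"))
  baseline <- net_gwp_per_cu(stages, seq_kg_per_cu)
  net <- switch(s$id,
    S1_conservative_seq =
      gross_emissions_per_cu(stages) - s$params$seq_factor * seq_kg_per_cu,
    S2_optimized_cultivation =
      baseline - s$params$energy_reduction *
        stages$contributions[["cultivation_energy"]],
    S3_ground_application =
      baseline + s$params$emission_delta_kg_per_cu,
    S4_high_pc_content = {
      if (s$params$y_new <= 0 || s$params$y_new > 1) {
        stop("scenario yield must be in (0, 1]", call. = FALSE)
      }
      baseline * y_base / s$params$y_new
    })
  list(id = s$id, net_kg_per_cu = net,
       pct_change = pct_change_from_baseline(net, baseline))
}

#' Run all four scenarios
#'
#' @inheritParams run_scenario
#' @return `data.frame` with columns `scenario, net_kg_per_cu, pct_change`.
#' @export
scenario_table <- function(stages = stage_profile(),
                           seq_kg_per_cu = canonical_sequestration_kg_per_cu(),
                           y_base = 0.0322) {
  ids <- c("S1_conservative_seq", "S2_optimized_cultivation",
           "S3_ground_application", "S4_high_pc_content")
  rows <- lapply(ids, function(id) {
    r <- run_scenario(scenario_spec(id), stages, seq_kg_per_cu, y_base)
    data.frame(scenario = r$id, net_kg_per_cu = r$net_kg_per_cu,
               pct_change = r$pct_change)
  })
  do.call(rbind, rows)
}

#' Percent reduction in carbon-negative potential
#'
#' `(|a| - |b|) / |a| * 100`: how much of the magnitude of footprint `a` is
#' lost when moving to footprint `b`. The baseline-to-high-pigment-content
#' comparison gives 83.9%.
#'
#' @param a reference footprint, kg CO2-eq (nonzero).
#' @param b comparison footprint, kg CO2-eq.
#' @return Percentage of `|a|` lost.
#' @export
percent_reduction <- function(a, b) {
  if (a == 0) stop("reference footprint must be nonzero", call. = FALSE)
  (abs(a) - abs(b)) / abs(a) * 100
}
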