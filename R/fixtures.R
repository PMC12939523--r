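## Canonical fixture tables, defined in code and written out by
## make_fixtures(). The inventory and recipe are the published life-cycle
## tables; stage labels come from the inventory's own comments column
## ("shared" where a flow serves multiple processes). The ingredient
## emission-factor table is SYNTHETIC: plausible stand-in magnitudes so the
## case study runs without background-database access.

#' Canonical per-CU life-cycle inventory
#'
#' The 26-flow inventory for producing one color unit of phycocyanin and
#' applying its waste stream as a biostimulant. The two elementary CO2 flows
#' (cultivation biofixation 0.40179 kg; soil carbon sequestration 1.60248 t)
#' carry `direction_sign = -1`.
#'
#' @return An [inventory_table()].
#' @export
table1_inventory <- function() {
  inventory_table(
    flow_name = c(
      "Aluminum, cast alloy [GLO]", "Battery, Li-ion [GLO]", "Cable [GLO]",
      "CO_2", "CO_2", "Diesel [GLO]",
      "Electricity, high voltage [IS]", "Electricity, medium voltage [IS]",
      "Electronics, for control units [RER]",
      "Glass-fiber-reinforced plastic, polyamide [RER]",
      "Iron sulfate [GLO]", "Land occupation",
      "Light-Emitting Diode (LED) [GLO]", "Nitrogen fertilizer, as N [GLO]",
      "Nylon 6-6 [RoW]", "Polyethylene, high density [GLO]",
      "Polypropylene [GLO]", "Polyvinylchloride [GLO]",
      "Silicone, at plant [GLO]", "Sodium phosphate [RoW]",
      "Steel, chromium steel 18/8 [GLO]", "Steel, unalloyed [RER]",
      "Tap water [IS]", "Transport, freight, lorry 16-32 ton [GLO]",
      "Transport, freight, lorry 3.5-7.5 ton [GLO]",
      "Transport, freight, transoceanic ship [GLO]"),
    amount = c(0.00434, 0.00011, 1.83251e-05, 0.40179, 1.60248, 8.13974,
               1.76167, 118.38543, 0.00641, 0.00594, 2.23214e-05, 0.00320,
               0.00538, 0.01116, 2.19901e-06, 0.00011, 0.00014, 0.00141,
               0.00012, 0.00893, 0.00242, 0.00155, 37.29687, 6.96354e-05,
               1.75961, 0.00443),
    unit = c("kg", "kg", "kg", "kg", "t", "MJ", "MJ", "MJ", "kg", "kg",
             "kg", "m2.a", "kg", "kg", "kg", "kg", "kg", "kg", "kg", "kg",
             "kg", "kg", "kg", "t.km", "t.km", "t.km"),
    compartment = c("technosphere", "technosphere", "technosphere",
                    "elementary", "elementary", "technosphere",
                    "technosphere", "technosphere", "technosphere",
                    "technosphere", "technosphere", "elementary",
                    "technosphere", "technosphere", "technosphere",
                    "technosphere", "technosphere", "technosphere",
                    "technosphere", "technosphere", "technosphere",
                    "technosphere", "technosphere", "technosphere",
                    "technosphere", "technosphere"),
    direction_sign = c(1, 1, 1, -1, -1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1,
                       1, 1, 1, 1, 1, 1, 1, 1, 1),
    stage = c("cultivation", "application", "application", "cultivation",
              "sequestration", "application", "shared", "shared", "shared",
              "shared", "cultivation", "cultivation", "cultivation",
              "cultivation", "application", "shared", "cultivation",
              "cultivation", "cultivation", "cultivation", "cultivation",
              "cultivation", "shared", "shared", "shared", "shared"),
    data_source = c("EcoInvent 3.9", "EcoInvent 3.9", "EcoInvent 3.9",
                    "Elementary flow", "Elementary flow", "EcoInvent 3.9",
                    "EcoInvent 3.9", "EcoInvent 3.9", "EcoInvent 3.9",
                    "EcoInvent 3.9", "EcoInvent 3.9", "Elementary flow",
                    "EcoInvent 3.9", "EcoInvent 3.9", "EcoInvent 3.9",
                    "EcoInvent 3.9", "EcoInvent 3.9", "EcoInvent 3.9",
                    "EcoInvent 3.9", "EcoInvent 3.9", "EcoInvent 3.9",
                    "EcoInvent 3.9", "EcoInvent 3.9", "EcoInvent 3.9",
                    "EcoInvent 3.9", "EcoInvent 3.9"),
    comment = c("For bioreactor production", "For drone production",
                "For drone production", "For cultivation",
                "Carbon sequestration", "For drone operation",
                "Used in multiple processes", "Used in multiple processes",
                "Used in multiple processes", "Used in multiple processes",
                "Nutrients", "For cultivation", "For bioreactor production",
                "Nutrients", "For drone production",
                "Used in multiple processes", "For bioreactor production",
                "For bioreactor production", "For bioreactor production",
                "Nutrients", "For bioreactor production",
                "For bioreactor production", "Used in multiple processes",
                "Used in multiple processes", "Used in multiple processes",
                "Used in multiple processes"))
}

#' Chocolate dragee recipe (100 g bag)
#'
#' Raw ingredients, a production-overhead marker row, and packaging entries.
#'
#' @return A `product_recipe`.
#' @export
table2_recipe <- function() {
  r <- data.frame(
    ingredient = c("milk_chocolate", "sugar_from_sugarcane",
                   "corn_glucose_syrup", "turmeric", "potato_starch",
                   "spirulina_dried", "sugarcane_processing",
                   "boiling_industrial", "beetroot_juice", "carrot_juice",
                   "dragee_production", "pet_granulate", "pp_granulate",
                   "extrusion_plastic_film", "ldpe_granulate"),
    mass_kg = c(0.067, 0.027, 0.004, 0.0001, 0.0015, 0.0001, 0.0001,
                0.0001, 0.0001, 0.0001, NA, 0.005, 0.004, 0.01, 0.001),
    role = c(rep("raw", 10), "production", rep("packaging", 4)),
    stringsAsFactors = FALSE)
  class(r) <- c("product_recipe", "data.frame")
  r
}

#' Synthetic ingredient emission factors
#'
#' Stand-in factors (kg CO2-eq per kg) of plausible magnitude for the dragee
#' recipe. They are NOT the background-database values used in practice; the
#' case-study product footprint is therefore illustrative, and users supply
#' their own factors for real assessments.
#'
#' @return Named numeric vector, ingredient -> kg CO2-eq per kg.
#' @export
synthetic_ingredient_factors <- function() {
  c(milk_chocolate = 7.0, sugar_from_sugarcane = 0.6,
    corn_glucose_syrup = 1.2, turmeric = 2.0, potato_starch = 1.0,
    spirulina_dried = 15.0, sugarcane_processing = 0.5,
    boiling_industrial = 0.3, beetroot_juice = 1.0, carrot_juice = 1.0,
    pet_granulate = 2.5, pp_granulate = 1.8, extrusion_plastic_film = 0.45,
    ldpe_granulate = 2.0)
}

#' Stage-level climate intensities per CU
#'
#' The pre-characterized stage intensities used by the net-footprint layer:
#' cultivation 0.15, extraction 4.83, sequestration -1602.48 kg CO2-eq/CU.
#'
#' @return `data.frame` with columns `stage, climate_kg_co2e_per_cu`.
#' @export
stage_intensities <- function() {
  data.frame(stage = c("cultivation", "extraction", "sequestration"),
             climate_kg_co2e_per_cu = c(0.15, 4.83, -1602.48),
             stringsAsFactors = FALSE)
}

#' Minimal GWP100 factor table
#'
#' Unit factor for elementary CO2 (1 kg CO2-eq per kg). Per-flow factors for
#' technosphere flows are a user input.
#'
#' @return A `cf_table`.
#' @export
gwp_factor_table <- function() {
  cf_table("CO_2", "climate_GWP100", 1.0, "kg CO2-eq per kg")
}

#' Write fixture files
#'
#' Writes the canonical inventory, recipe, stage intensities, GWP factor
#' table, synthetic ingredient factors and the default YAML config to
#' `outdir`. Output is byte-stable: two runs give identical files.
#'
#' @param outdir writable output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
make_fixtures <- function(outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(outdir, c("inventory_table1.csv", "recipe_table2.csv",
                               "stage_intensities.csv", "gwp_factors.csv",
                               "synthetic_ingredient_factors.csv",
                               "default_config.yaml"))
  utils::write.csv(table1_inventory(), paths[1], row.names = FALSE)
  utils::write.csv(table2_recipe(), paths[2], row.names = FALSE)
  utils::write.csv(stage_intensities(), paths[3], row.names = FALSE)
  utils::write.csv(gwp_factor_table(), paths[4], row.names = FALSE)
  ef <- synthetic_ingredient_factors()
  utils::write.csv(data.frame(ingredient = names(ef),
                              kg_co2e_per_kg = unname(ef)),
                   paths[5], row.names = FALSE)
  yaml::write_yaml(default_config(), paths[6])
  invisible(paths)
}

#' Path to a shipped fixture file
#'
#' @param file file name under the package's `extdata` directory; with no
#'   argument, lists the available fixtures.
#' @return A file path (or vector of file names).
#' @export
phyco_extdata <- function(file = NULL) {
  dir <- system.file("extdata", package = "phycocarbon")
  if (is.null(file)) return(list.files(dir))
  path <- file.path(dir, file)
  if (!file.exists(path)) stop("no such fixture: ", file, call. = FALSE)
  path
}
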