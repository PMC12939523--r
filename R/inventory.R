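## Life-cycle inventory data model and linear characterization.
##
## An inventory table holds per-functional-unit flow amounts; all amounts are
## stored non-negative and the emission/removal sign lives in direction_sign
## (+1 emission or input, -1 removal/uptake), so printed source amounts are
## preserved verbatim.

#' Controlled unit vocabulary for inventory flows
#'
#' Units accepted in inventory tables. Mass units are converted to kg before
#' characterization (`t` x1000, `g` x0.001); the remaining units (`MJ`,
#' `t.km`, `m2.a`, `L`, `item`) are already the base unit their
#' characterization factors are expressed per.
#'
#' @return Character vector of valid unit symbols.
#' @export
inventory_units <- function() {
  c("kg", "t", "g", "MJ", "t.km", "m2.a", "L", "item")
}

## multiplicative conversion to the SI/base unit of each flow
.unit_to_base <- c(kg = 1, t = 1000, g = 0.001, MJ = 1,
                   "t.km" = 1, "m2.a" = 1, L = 1, item = 1)

#' Build and validate an inventory table
#'
#' @param flow_name character; flow identifier, matched against
#'   characterization factor tables.
#' @param amount numeric, finite and non-negative; magnitudes only, the sign
#'   is carried by `direction_sign`.
#' @param unit character, one of [inventory_units()].
#' @param compartment `"technosphere"` (purchased goods, energy, transport)
#'   or `"elementary"` (direct exchanges with the environment).
#' @param direction_sign `+1` for emissions/inputs, `-1` for
#'   removals/uptake (e.g. biofixation, soil carbon sequestration).
#' @param stage optional production-stage label per flow.
#' @param data_source,comment optional free-text provenance columns.
#' @return A `data.frame` of class `"inventory_table"`.
#' @export
inventory_table <- function(flow_name, amount, unit, compartment,
                            direction_sign, stage = NA_character_,
                            data_source = NA_character_,
                            comment = NA_character_) {
  inv <- data.frame(flow_name = as.character(flow_name),
                    amount = as.numeric(amount),
                    unit = as.character(unit),
                    compartment = as.character(compartment),
                    direction_sign = as.integer(direction_sign),
                    stage = as.character(stage),
                    data_source = as.character(data_source),
                    comment = as.character(comment),
                    stringsAsFactors = FALSE)
  validate_inventory(inv)
}

validate_inventory <- function(inv) {
  bad_unit <- !(inv$unit %in% inventory_units())
  if (any(bad_unit)) {
    stop("unknown unit(s) in inventory rows ",
         paste(which(bad_unit), collapse = ", "), ": ",
         paste(unique(inv$unit[bad_unit]), collapse = ", "),
         "; allowed: ", paste(inventory_units(), collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(inv$amount))) {
    stop("non-finite amount in inventory rows ",
         paste(which(!is.finite(inv$amount)), collapse = ", "), call. = FALSE)
  }
  if (any(inv$amount < 0)) {
    stop("negative amount in inventory rows ",
         paste(which(inv$amount < 0), collapse = ", "),
         "; encode removals via direction_sign = -1, not negative amounts",
         call. = FALSE)
  }
  if (any(!inv$compartment %in% c("technosphere", "elementary"))) {
    stop("compartment must be 'technosphere' or 'elementary'", call. = FALSE)
  }
  if (any(!inv$direction_sign %in% c(-1L, 1L))) {
    stop("direction_sign must be +1 or -1", call. = FALSE)
  }
  class(inv) <- c("inventory_table", "data.frame")
  inv
}

#' Read an inventory table from CSV
#'
#' Expected columns: `flow_name, amount, unit, compartment, direction_sign`
#' and optionally `stage, data_source, comment`. An empty file with a valid
#' header yields an empty (zero-row) table.
#'
#' @param path path to a UTF-8 CSV with `.` decimal separator.
#' @return An `inventory_table`.
#' @export
read_inventory <- function(path) {
  if (!file.exists(path)) stop("inventory file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(amount = "numeric"))
  needed <- c("flow_name", "amount", "unit", "compartment", "direction_sign")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    stop("inventory file ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (opt in c("stage", "data_source", "comment")) {
    if (is.null(raw[[opt]])) raw[[opt]] <- rep(NA_character_, nrow(raw))
  }
  validate_inventory(raw[, c(needed, "stage", "data_source", "comment")])
}

#' Read a characterization factor table from CSV
#'
#' Columns: `flow_name, category, factor, factor_unit`. Factors are expressed
#' per base unit of the flow (per kg for mass flows, per MJ, per t.km, ...),
#' e.g. kg CO2-eq per kg for `climate_GWP100`.
#'
#' @param path path to the factor CSV.
#' @return A `data.frame` of class `"cf_table"`.
#' @export
read_factors <- function(path) {
  if (!file.exists(path)) stop("factor file not found: ", path, call. = FALSE)
  cf <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("flow_name", "category", "factor")
  if (!all(needed %in% names(cf))) {
    stop("factor file must have columns flow_name, category, factor", call. = FALSE)
  }
  if (is.null(cf$factor_unit)) cf$factor_unit <- NA_character_
  cf_table(cf$flow_name, cf$category, cf$factor, cf$factor_unit)
}

#' Build a characterization factor table
#'
#' @param flow_name,category,factor,factor_unit vectors defining one
#'   (flow, impact category) -> factor entry per element.
#' @return A `data.frame` of class `"cf_table"`.
#' @export
cf_table <- function(flow_name, category, factor, factor_unit = NA_character_) {
  cf <- data.frame(flow_name = as.character(flow_name),
                   category = as.character(category),
                   factor = as.numeric(factor),
                   factor_unit = as.character(factor_unit),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(cf[, c("flow_name", "category")])) {
    stop("duplicate (flow_name, category) pair in factor table", call. = FALSE)
  }
  if (any(!is.finite(cf$factor))) stop("non-finite characterization factor", call. = FALSE)
  class(cf) <- c("cf_table", "data.frame")
  cf
}

#' Convert inventory amounts to base units
#'
#' @param inv an `inventory_table`.
#' @return Numeric vector of amounts in base units (kg for mass flows).
#' @export
amount_in_base_units <- function(inv) {
  inv$amount * unname(.unit_to_base[inv$unit])
}

#' Characterize an inventory into per-category impact totals
#'
#' Linear aggregation: each category total is
#' `sum(amount_base * direction_sign * factor)` over flows with a factor for
#' that category. Elementary flows lacking a factor for a requested category
#' must appear in `ignore`, otherwise a hard error lists them — missing pairs
#' are never treated as silent zeros. Technosphere flows without a factor are
#' skipped and recorded in the `uncharacterized` attribute (a full per-flow
#' background database is a user input, not shipped).
#'
#' @param inv an `inventory_table`.
#' @param cf a `cf_table`.
#' @param categories impact categories to compute; defaults to those present
#'   in `cf`.
#' @param ignore character vector of elementary flow names deliberately left
#'   uncharacterized.
#' @return An `impact_result`: list with `totals` (named numeric) and
#'   `breakdown` (stage x category matrix).
#' @export
characterize <- function(inv, cf, categories = unique(cf$category),
                         ignore = character()) {
  stopifnot(inherits(inv, "inventory_table"), inherits(cf, "cf_table"))
  base_amt <- amount_in_base_units(inv)
  signed <- base_amt * inv$direction_sign
  stage <- ifelse(is.na(inv$stage), "unassigned", inv$stage)
  stages <- unique(stage)
  breakdown <- matrix(0, nrow = length(stages), ncol = length(categories),
                      dimnames = list(stages, categories))
  unchar <- character()
  for (cat in categories) {
    fmap <- cf[cf$category == cat, ]
    idx <- match(inv$flow_name, fmap$flow_name)
    missing <- is.na(idx)
    bad <- missing & inv$compartment == "elementary" &
      !(inv$flow_name %in% ignore)
    if (any(bad)) {
      stop("no ", cat, " factor for elementary flow(s): ",
           paste(unique(inv$flow_name[bad]), collapse = ", "),
           "; supply factors or list them in `ignore`", call. = FALSE)
    }
    unchar <- union(unchar, inv$flow_name[missing & inv$compartment == "technosphere"])
    contrib <- ifelse(missing, 0, signed * fmap$factor[idx])
    breakdown[, cat] <- vapply(stages, function(s) sum(contrib[stage == s]),
                               numeric(1))
  }
  impact_result(colSums(breakdown), breakdown, uncharacterized = unchar)
}

#' Construct an impact result
#'
#' @param totals named numeric vector of per-category totals.
#' @param breakdown stage x category numeric matrix summing to `totals`.
#' @param uncharacterized flows skipped for lack of factors.
#' @return Object of class `"impact_result"`.
#' @export
impact_result <- function(totals, breakdown = NULL, uncharacterized = character()) {
  if (is.null(breakdown)) {
    breakdown <- matrix(totals, nrow = 1,
                        dimnames = list("total", names(totals)))
  }
  stopifnot(all(abs(colSums(breakdown) - totals) <=
                  1e-9 * pmax(abs(totals), 1)))
  structure(list(totals = totals, breakdown = breakdown,
                 uncharacterized = uncharacterized),
            class = "impact_result")
}

#' @export
print.impact_result <- function(x, ...) {
  cat("Impact result (per functional unit)\n")
  for (nm in names(x$totals)) {
    cat(sprintf("  %-18s %12.4f\n", nm, x$totals[[nm]]))
  }
  if (nrow(x$breakdown) > 1) {
    cat("Stage breakdown:\n")
    print(round(x$breakdown, 4))
  }
  if (length(x$uncharacterized) > 0) {
    cat("Uncharacterized technosphere flows:",
        paste(x$uncharacterized, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Per-stage impact totals
#'
#' Characterizes an inventory with every flow assigned to exactly one stage;
#' a flow without a stage label is a hard error (unlike [characterize()],
#' which pools unlabelled flows under "unassigned").
#'
#' @inheritParams characterize
#' @param stage_labels optional named character vector flow_name -> stage,
#'   overriding the table's own `stage` column.
#' @return An `impact_result` whose breakdown rows are the stages.
#' @export
stage_totals <- function(inv, cf, stage_labels = NULL,
                         categories = unique(cf$category),
                         ignore = character()) {
  if (!is.null(stage_labels)) {
    inv$stage <- unname(stage_labels[inv$flow_name])
  }
  if (any(is.na(inv$stage))) {
    stop("flow(s) without a stage label: ",
         paste(unique(inv$flow_name[is.na(inv$stage)]), collapse = ", "),
         call. = FALSE)
  }
  characterize(inv, cf, categories = categories, ignore = ignore)
}
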