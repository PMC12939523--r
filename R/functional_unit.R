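## Color-unit arithmetic and the product/waste mass balance.
##
## The functional unit of the assessment is 1 color unit (CU) of phycocyanin
## extract at factory gate, equivalent to 7.12 g of pigment at a strength of
## roughly 140 CU/kg. The two constants are mutually inconsistent by ~0.3%
## (1000/140 = 7.143): 7.12 g/CU is treated as canonical because the
## downstream carbon balance is built on it, and 140 CU/kg is display
## metadata only.

#' Color value of a phycocyanin extract
#'
#' Industrial color units per kg from absorbance at 618 nm:
#' `CU/kg = A618 * 10 * DF / (g * 100)` with `DF` the dilution factor and
#' `g` the sample mass in grams.
#'
#' @param a618 absorbance at 618 nm (dimensionless, >= 0).
#' @param df dilution factor (>= 1).
#' @param sample_mass_g sample mass in grams (> 0).
#' @return Color value in CU per kg.
#' @examples
#' color_value(0.7, 100, 0.05)  # 140 CU/kg
#' @export
color_value <- function(a618, df, sample_mass_g) {
  stopifnot(is.finite(a618), is.finite(df), is.finite(sample_mass_g))
  if (a618 < 0) stop("absorbance must be non-negative", call. = FALSE)
  if (df < 1) stop("dilution factor must be >= 1", call. = FALSE)
  if (sample_mass_g <= 0) stop("sample mass must be positive grams", call. = FALSE)
  a618 * 10 * df / (sample_mass_g * 100)
}

#' Grams of phycocyanin per color unit
#'
#' Inverse of the extract strength: `1000/strength` grams per CU. With
#' `strength = NULL` the canonical constant 7.12 g/CU is returned.
#'
#' @param strength extract strength in CU per kg, or `NULL` for the canonical
#'   7.12 g/CU.
#' @return Grams of phycocyanin per CU.
#' @export
pigment_mass_per_cu <- function(strength = NULL) {
  if (is.null(strength)) return(7.12)
  if (!is.finite(strength) || strength <= 0) {
    stop("strength must be a positive CU/kg value", call. = FALSE)
  }
  1000 / strength
}

#' Mass-balance parameters per functional unit
#'
#' @param m_pc_per_cu grams of phycocyanin per CU (default 7.12).
#' @param y_pc pigment extraction yield as a fraction of dry biomass
#'   (default 0.0322).
#' @param f_w biostimulant waste fraction of dry biomass (default 0.158).
#' @param strength extract strength in CU/kg, display metadata (default 140).
#' @return List of class `"mass_balance_params"`.
#' @export
mass_balance_params <- function(m_pc_per_cu = 7.12, y_pc = 0.0322,
                                f_w = 0.158, strength = 140) {
  stopifnot(is.finite(m_pc_per_cu), is.finite(y_pc), is.finite(f_w))
  if (m_pc_per_cu <= 0) stop("m_pc_per_cu must be positive", call. = FALSE)
  if (y_pc <= 0 || y_pc > 1) stop("y_pc must be in (0, 1]", call. = FALSE)
  if (f_w < 0 || f_w > 1) stop("f_w must be in [0, 1]", call. = FALSE)
  if (y_pc + f_w > 1) {
    stop("pigment yield plus waste fraction cannot exceed the dry biomass",
         call. = FALSE)
  }
  structure(list(m_pc_per_cu = m_pc_per_cu, y_pc = y_pc, f_w = f_w,
                 strength = strength), class = "mass_balance_params")
}

#' Dry-biomass, pigment and waste masses per color unit
#'
#' One CU requires `m_pc_per_cu / y_pc` grams of dry Spirulina biomass; the
#' soluble waste stream available as biostimulant is `f_w` of that dry mass.
#' With the defaults (7.12 g/CU, 3.22% yield, 15.8% waste) this gives about
#' 221.1 g dry biomass and 34.94 g waste per CU.
#'
#' @param p a [mass_balance_params()] object.
#' @return List with `dry_biomass_g_per_cu`, `phycocyanin_g_per_cu`,
#'   `waste_g_per_cu` (all grams per CU).
#' @export
mass_balance_per_cu <- function(p = mass_balance_params()) {
  stopifnot(inherits(p, "mass_balance_params"))
  dry <- p$m_pc_per_cu / p$y_pc
  list(dry_biomass_g_per_cu = dry,
       phycocyanin_g_per_cu = p$m_pc_per_cu,
       waste_g_per_cu = p$f_w * dry)
}
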