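# Productivity metrics: wheat-equivalent yield, CPI-deflated economic
# benefit, protein yield, nutrition yield, and rotation annualization.

#' Wheat-equivalent yield
#'
#' Re-expresses a crop's yield in winter-wheat units via the price ratio:
#' `EY = yield x price / wheat_price`, so crops with very different
#' products (grain, tubers, forage) become comparable.
#'
#' @param yield_kg_ha crop yield (kg/ha, at commercial moisture).
#' @param price crop market price (currency/kg).
#' @param wheat_price winter wheat price in the same year (currency/kg,
#'   > 0).
#' @return Equivalent yield, kg/ha (vectorized).
#' @examples
#' equivalent_yield(5000, 7, 2.8)  # 12500
#' @export
equivalent_yield <- function(yield_kg_ha, price, wheat_price) {
  if (any(wheat_price <= 0)) stop("wheat price must be positive")
  if (any(yield_kg_ha < 0) || any(price < 0)) {
    stop("yield and price must be non-negative")
  }
  yield_kg_ha * price / wheat_price
}

#' Economic benefit (net income), deflated by a consumer price index
#'
#' `EB = yield x price x CPI_j / CPI_base - cost`, in currency/ha. The
#' CPI ratio removes inflation between years so incomes from different
#' seasons are comparable in base-year terms.
#'
#' @param yield_kg_ha crop yield (kg/ha).
#' @param price crop price (currency/kg).
#' @param cost production cost (currency/ha).
#' @param year harvest year (must be present in `cpi`).
#' @param cpi data frame with columns `year` and `cpi`.
#' @param base_year CPI reference year (default 2008).
#' @return Net income, currency/ha (vectorized over records).
#' @export
economic_benefit <- function(yield_kg_ha, price, cost, year, cpi,
                             base_year = 2008) {
  if (!base_year %in% cpi$year) {
    stop("CPI series does not contain the base year ", base_year)
  }
  idx <- match(year, cpi$year)
  if (anyNA(idx)) {
    stop("CPI series does not contain year(s): ",
         paste(unique(year[is.na(idx)]), collapse = ", "))
  }
  deflator <- cpi$cpi[idx] / cpi$cpi[match(base_year, cpi$year)]
  yield_kg_ha * price * deflator - cost
}

#' Protein yield
#'
#' `PC = yield x beta` where `beta` is the protein mass fraction of the
#' harvested product.
#'
#' @param yield_kg_ha crop yield (kg/ha).
#' @param beta protein fraction in `[0, 1]`.
#' @return Protein yield, kg/ha (vectorized).
#' @examples
#' protein_yield(6000, 0.13)  # 780
#' @export
protein_yield <- function(yield_kg_ha, beta) {
  if (any(beta < 0 | beta > 1)) stop("beta must lie in [0, 1]")
  yield_kg_ha * beta
}

#' Composite nutrition yield across rotations
#'
#' Per-nutrient yield of a rotation is the sum over its crops of annual
#' yield times concentration; the composite score min--max normalizes each
#' nutrient's yield across rotations and averages them with the supplied
#' weights (equal by default). A nutrient constant across all rotations
#' carries no ranking information and is scored 0.5 everywhere.
#'
#' @param crop_yields data frame with columns `rotation`, `crop`,
#'   `yield_kg_ha` (annualized mean yield of each crop in each rotation).
#' @param nutrient_table data frame with a `crop` column and one numeric
#'   column per nutritional component (per-kg concentrations).
#' @param weights optional named weights over nutrients, summing to 1.
#' @return List: `nutrient_yields` (rotation x nutrient matrix, kg/ha/yr),
#'   `normalized`, `composite` (named vector in `[0, 1]`).
#' @export
nutrition_yield <- function(crop_yields, nutrient_table, weights = NULL) {
  nutrients <- setdiff(names(nutrient_table), "crop")
  if (!length(nutrients)) stop("nutrient table has no component columns")
  idx <- match(crop_yields$crop, nutrient_table$crop)
  if (anyNA(idx)) {
    stop("nutrient table is missing crop(s): ",
         paste(unique(crop_yields$crop[is.na(idx)]), collapse = ", "))
  }
  conc <- as.matrix(nutrient_table[idx, nutrients, drop = FALSE])
  contrib <- conc * crop_yields$yield_kg_ha
  ny <- rowsum(contrib, crop_yields$rotation, reorder = FALSE)
  if (is.null(weights)) {
    weights <- setNames(rep(1 / length(nutrients), length(nutrients)),
                        nutrients)
  }
  if (!setequal(names(weights), nutrients)) {
    stop("weights must be named after the nutrient columns")
  }
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1")
  norm <- apply(ny, 2, function(x) {
    r <- range(x)
    if (diff(r) == 0) rep(0.5, length(x)) else (x - r[1]) / diff(r)
  })
  if (is.null(dim(norm))) norm <- matrix(norm, nrow = nrow(ny),
                                         dimnames = dimnames(ny))
  composite <- drop(norm[, nutrients, drop = FALSE] %*% weights[nutrients])
  list(nutrient_yields = ny, normalized = norm,
       composite = setNames(composite, rownames(ny)))
}

#' Annualize cycle totals of a rotation
#'
#' Indicators are summed over the crops of one rotation cycle and divided
#' by the cycle length in years, so 1- and 2-year rotations are compared
#' on a per-year basis. Fallow seasons simply contribute nothing to the
#' sum.
#'
#' @param values per-crop values over exactly one cycle (kg/ha,
#'   currency/ha, ...).
#' @param cycle_years cycle length (> 0).
#' @param rotation optional rotation labels for the records; mixing
#'   rotations is an error.
#' @return Annualized value (cycle sum / cycle years).
#' @examples
#' annualize_rotation(c(18000, 13000), 2)  # 15500
#' @export
annualize_rotation <- function(values, cycle_years, rotation = NULL) {
  if (cycle_years <= 0) stop("cycle_years must be > 0")
  if (!is.null(rotation) && length(unique(rotation)) > 1) {
    stop("records from more than one rotation: ",
         paste(unique(rotation), collapse = ", "))
  }
  sum(values) / cycle_years
}
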