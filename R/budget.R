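# Indirect (life-cycle) emissions, soil organic carbon stocks and the net
# greenhouse-gas budget.

#' Indirect greenhouse-gas emissions from agricultural inputs
#'
#' Life-cycle CO2-equivalent cost of input manufacture, storage and
#' delivery to the farm gate: `CE = sum_k D_k * C_k` over input kinds,
#' annualized by the rotation cycle length. The system boundary ends at
#' crop harvest; downstream logistics are excluded.
#'
#' @param inventory data frame with columns `input_kind` and `amount`
#'   (native units per hectare over the cycle).
#' @param factors emission-factor table with columns `input_kind` and
#'   `kg_co2e_per_unit`; see [default_emission_factors()].
#' @param cycle_years cycle length used for annualization (default 1).
#' @return CE in kg CO2-eq/ha/yr.
#' @examples
#' indirect_emissions(data.frame(input_kind = "fert_n", amount = 200),
#'                    data.frame(input_kind = "fert_n",
#'                               kg_co2e_per_unit = 8.3))
#' @export
indirect_emissions <- function(inventory, factors, cycle_years = 1) {
  if (cycle_years <= 0) stop("cycle_years must be > 0")
  if (nrow(inventory) == 0) return(0)
  if (any(inventory$amount < 0)) stop("input amounts must be non-negative")
  idx <- match(inventory$input_kind, factors$input_kind)
  if (anyNA(idx)) {
    stop("no emission factor for input kind(s): ",
         paste(unique(inventory$input_kind[is.na(idx)]), collapse = ", "))
  }
  ck <- factors$kg_co2e_per_unit[idx]
  if (any(ck < 0)) stop("emission factors must be non-negative")
  sum(inventory$amount * ck) / cycle_years
}

#' Soil organic carbon stock of a layered profile
#'
#' `stock = sum_layers conc (g/kg) x bulk density (g/cm^3) x
#' thickness (cm) x 0.1`, in t C/ha. Layers must be contiguous,
#' non-overlapping and ordered by depth.
#'
#' @param profile data frame with columns `top_cm`, `bottom_cm`,
#'   `soc_g_kg`, `bd_g_cm3`.
#' @return Total stock (t C/ha) with attribute `"layers"`: the input
#'   augmented with per-layer `stock_t_ha`.
#' @examples
#' soc_stock(data.frame(top_cm = 0, bottom_cm = 10,
#'                      soc_g_kg = 11.5, bd_g_cm3 = 1.49))  # 17.135
#' @export
soc_stock <- function(profile) {
  need <- c("top_cm", "bottom_cm", "soc_g_kg", "bd_g_cm3")
  miss <- setdiff(need, names(profile))
  if (length(miss)) stop("profile is missing column(s): ",
                         paste(miss, collapse = ", "))
  profile <- profile[order(profile$top_cm), , drop = FALSE]
  if (any(profile$bottom_cm <= profile$top_cm)) {
    stop("every layer must have bottom_cm > top_cm")
  }
  n <- nrow(profile)
  if (n > 1 && any(profile$top_cm[-1] != profile$bottom_cm[-n])) {
    stop("missing or overlapping layer: profile must be contiguous")
  }
  if (any(profile$soc_g_kg < 0) || any(profile$bd_g_cm3 <= 0)) {
    stop("SOC concentrations must be >= 0 and bulk densities > 0")
  }
  profile$stock_t_ha <- profile$soc_g_kg * profile$bd_g_cm3 *
    (profile$bottom_cm - profile$top_cm) * 0.1
  total <- sum(profile$stock_t_ha)
  attr(total, "layers") <- profile
  total
}

#' Cumulative SOC stock fraction above given depths
#'
#' Fraction of the whole-profile stock held above each depth (e.g. the
#' share of 0--90 cm carbon found in the top 20 cm). Depths must coincide
#' with layer boundaries.
#'
#' @param profile as in [soc_stock()].
#' @param depths_cm depths of interest (default 20, 30, 50).
#' @return Named vector of fractions in (0, 1].
#' @export
soc_depth_shares <- function(profile, depths_cm = c(20, 30, 50)) {
  total <- soc_stock(profile)
  layers <- attr(total, "layers")
  bad <- setdiff(depths_cm, layers$bottom_cm)
  if (length(bad)) {
    stop("depth(s) not on a layer boundary: ", paste(bad, collapse = ", "))
  }
  shares <- vapply(depths_cm, function(d) {
    sum(layers$stock_t_ha[layers$bottom_cm <= d]) / as.numeric(total)
  }, 0)
  names(shares) <- sprintf("0-%gcm", depths_cm)
  shares
}

#' Annualized soil carbon stock change as CO2-equivalents
#'
#' `dC = (T2 - T1) x 44/12 / n_years x 1000` in kg CO2-eq/ha/yr, positive
#' when carbon accrues (the soil is a sink). 44/12 converts C mass to CO2
#' mass. The C-basis rate `(T2 - T1)/n_years` (t C/ha/yr) is returned
#' alongside.
#'
#' @param t1_t_ha whole-profile stock at the start (t C/ha).
#' @param t2_t_ha whole-profile stock at the end (t C/ha).
#' @param n_years length of the period (> 0).
#' @return List with `rate_t_c_ha_yr` and `delta_co2_kg_ha_yr`.
#' @examples
#' delta_soc(100, 112.18, 6)
#' @export
delta_soc <- function(t1_t_ha, t2_t_ha, n_years) {
  if (n_years <= 0) stop("n_years must be > 0")
  rate <- (t2_t_ha - t1_t_ha) / n_years
  list(rate_t_c_ha_yr = rate, delta_co2_kg_ha_yr = rate * 44 / 12 * 1000)
}

#' Net greenhouse-gas budget of a rotation
#'
#' `net = CE + GWP - dC`: indirect input emissions plus the warming
#' potential of soil N2O/CH4 fluxes minus soil carbon sequestration. The
#' offset fraction `dC / (CE + GWP)` reports how much of the gross
#' emission the soil sink cancels.
#'
#' @param ce indirect emissions (kg CO2-eq/ha/yr).
#' @param gwp_soil soil N2O + CH4 warming potential (kg CO2-eq/ha/yr).
#' @param delta_c soil carbon sequestration (kg CO2-eq/ha/yr, positive =
#'   sink).
#' @return List of class `"ghg_budget"`: `ce`, `gwp`, `delta_c`, `net`,
#'   `offset_fraction` (`NA` when `ce + gwp_soil <= 0`).
#' @examples
#' net_ghg(8802, 3764, 2541)$net  # 10025
#' @export
net_ghg <- function(ce, gwp_soil, delta_c) {
  gross <- ce + gwp_soil
  out <- list(ce = ce, gwp = gwp_soil, delta_c = delta_c,
              net = gross - delta_c,
              offset_fraction = ifelse(gross > 0, delta_c / gross, NA_real_))
  class(out) <- "ghg_budget"
  out
}
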