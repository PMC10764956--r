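# Static-chamber flux calculation, time integration and CO2-equivalents.

#' Reference constants for chamber flux calculation
#'
#' Ideal-gas reference state used to convert a headspace concentration
#' slope into an area-scaled mass flux: molar volume `V0` (m^3/mol) at
#' standard temperature `T0` (K) and pressure `P0` (kPa), and molecular
#' masses `M` (g/mol) for N2O and CH4.
#'
#' @return A list with elements `V0`, `T0`, `P0` and named vector `M`.
#' @export
flux_constants <- function() {
  list(V0 = 0.022414, T0 = 273.15, P0 = 101.325, M = c(n2o = 44, ch4 = 16))
}

#' Fit a chamber flux from a closure concentration series
#'
#' Ordinary least-squares slope of headspace concentration (ppm) against
#' closure time (minutes), scaled to a mass flux
#' `f = (M/V0) (T0/T) (P/P0) H (dc/dt) 60` in ug m^-2 h^-1. Negative
#' fluxes are valid (CH4 uptake by the soil sink). No goodness-of-fit
#' rejection is applied unless `min_r2` is set; routine chamber QC is
#' available but off by default.
#'
#' @param t_min closure times in minutes (>= 3 strictly increasing values).
#' @param conc_ppm concentrations at each time (ppm).
#' @param T_K chamber air temperature (K).
#' @param P_kPa chamber air pressure (kPa).
#' @param H_m chamber height (m).
#' @param gas `"n2o"` or `"ch4"` (sets the molecular mass).
#' @param constants reference constants, see [flux_constants()].
#' @param min_r2 optional R^2 threshold; fits below it return `NA` flux.
#' @return A list: `flux_ug_m2_h`, `flux_kg_ha_h` (1 ug m^-2 h^-1 =
#'   1e-5 kg ha^-1 h^-1), `slope_ppm_min`, `r_squared`, `n`.
#' @examples
#' fit_flux(c(0, 12, 24, 36), c(0.320, 0.332, 0.344, 0.356),
#'          T_K = 298.15, P_kPa = 101.325, H_m = 0.3, gas = "n2o")
#' @export
fit_flux <- function(t_min, conc_ppm, T_K, P_kPa, H_m,
                     gas = c("n2o", "ch4"), constants = flux_constants(),
                     min_r2 = NULL) {
  gas <- match.arg(gas)
  if (length(t_min) < 3) stop("chamber series needs at least 3 time points")
  if (length(conc_ppm) != length(t_min)) stop("t_min and conc_ppm lengths differ")
  if (any(diff(t_min) <= 0)) stop("closure times must be strictly increasing")
  if (diff(range(t_min)) == 0) stop("zero time span in chamber series")
  if (T_K <= 0 || P_kPa <= 0 || H_m <= 0) {
    stop("chamber T, P and H must all be positive")
  }
  tc <- t_min - mean(t_min)
  cc <- conc_ppm - mean(conc_ppm)
  slope <- sum(tc * cc) / sum(tc^2)
  sst <- sum(cc^2)
  r2 <- if (sst == 0) 1 else sum((slope * tc)^2) / sst
  k <- constants$M[[gas]] / constants$V0 * (constants$T0 / T_K) *
    (P_kPa / constants$P0) * H_m * 60
  flux <- k * slope
  if (!is.null(min_r2) && r2 < min_r2) flux <- NA_real_
  list(flux_ug_m2_h = flux, flux_kg_ha_h = flux * 1e-5,
       slope_ppm_min = slope, r_squared = r2, n = length(t_min))
}

#' Fit fluxes for a whole chamber table
#'
#' Vectorized version of [fit_flux()] for a long-format chamber table, one
#' OLS fit per `plot` x `gas` x `date` group.
#'
#' @param chamber data frame with columns `plot`, `gas`, `date`, `t_min`,
#'   `conc_ppm`, `T_K`, `P_kPa`, `H_m` (extra columns such as `rotation`
#'   or `year` are carried through).
#' @param constants see [flux_constants()].
#' @param min_r2 optional QC threshold as in [fit_flux()].
#' @return A data frame with one row per chamber deployment: grouping
#'   columns plus `flux_ug_m2_h`, `flux_kg_ha_h`, `slope_ppm_min`,
#'   `r_squared`.
#' @export
fit_flux_table <- function(chamber, constants = flux_constants(),
                           min_r2 = NULL) {
  need <- c("plot", "gas", "date", "t_min", "conc_ppm", "T_K", "P_kPa", "H_m")
  miss <- setdiff(need, names(chamber))
  if (length(miss)) {
    stop("chamber table is missing column(s): ", paste(miss, collapse = ", "))
  }
  key <- interaction(chamber$plot, chamber$gas, chamber$date, drop = TRUE)
  ord <- order(key)
  chamber <- chamber[ord, ]
  key <- key[ord]
  # per-group centered regression, all groups at once
  t_bar <- ave(chamber$t_min, key)
  c_bar <- ave(chamber$conc_ppm, key)
  tc <- chamber$t_min - t_bar
  cc <- chamber$conc_ppm - c_bar
  sxy <- rowsum(tc * cc, key, reorder = FALSE)[, 1]
  sxx <- rowsum(tc * tc, key, reorder = FALSE)[, 1]
  syy <- rowsum(cc * cc, key, reorder = FALSE)[, 1]
  if (any(sxx == 0)) stop("zero time span in at least one chamber series")
  slope <- sxy / sxx
  r2 <- ifelse(syy == 0, 1, slope^2 * sxx / syy)
  first <- !duplicated(key)
  out <- chamber[first, setdiff(names(chamber), c("t_min", "conc_ppm")),
                 drop = FALSE]
  k <- constants$M[match(out$gas, names(constants$M))] / constants$V0 *
    (constants$T0 / out$T_K) * (out$P_kPa / constants$P0) * out$H_m * 60
  out$slope_ppm_min <- slope
  out$r_squared <- r2
  out$flux_ug_m2_h <- k * slope
  if (!is.null(min_r2)) out$flux_ug_m2_h[r2 < min_r2] <- NA_real_
  out$flux_kg_ha_h <- out$flux_ug_m2_h * 1e-5
  rownames(out) <- NULL
  out
}

#' Cumulative gas emission by trapezoidal integration
#'
#' Integrates a flux time series over a window with linear interpolation
#' between sampling dates:
#' `F = sum_i ((f_{i+1} + f_i)/2 * (t_{i+1} - t_i)) * 24` with flux in
#' kg ha^-1 h^-1 and time in days. The window boundaries are clipped onto
#' the piecewise-linear interpolant.
#'
#' @param dates sampling dates (`Date` or numeric days), strictly increasing.
#' @param flux_kg_ha_h fluxes at those dates (kg ha^-1 h^-1).
#' @param from,to optional integration window; defaults to the full series.
#' @return Cumulative emission in kg/ha over the window.
#' @examples
#' cumulative_emission(c(0, 7), c(1e-4, 1e-4))  # 0.0168 kg/ha
#' @export
cumulative_emission <- function(dates, flux_kg_ha_h, from = NULL, to = NULL) {
  t <- as.numeric(dates)
  f <- as.numeric(flux_kg_ha_h)
  if (length(t) != length(f)) stop("dates and fluxes have different lengths")
  if (length(t) < 2) stop("at least 2 flux observations are required")
  if (any(diff(t) <= 0)) stop("sampling dates must be strictly increasing")
  if (anyNA(f)) stop("flux series contains missing values")
  a <- if (is.null(from)) t[1] else max(as.numeric(from), t[1])
  b <- if (is.null(to)) t[length(t)] else min(as.numeric(to), t[length(t)])
  if (b <= a) stop("integration window is empty")
  inside <- t > a & t < b
  tt <- c(a, t[inside], b)
  ff <- c(approx(t, f, xout = a)$y, f[inside], approx(t, f, xout = b)$y)
  if (length(tt) < 2) stop("fewer than 2 points inside the window")
  sum((ff[-1] + ff[-length(ff)]) / 2 * diff(tt)) * 24
}

#' 100-year global warming potential of soil N2O and CH4 emissions
#'
#' `GWP = N2O x 273 + CH4 x 27` in kg CO2-eq, with both inputs as species
#' masses (kg N2O, kg CH4 -- not element masses). A negative CH4 term
#' (soil methane sink) reduces the total.
#'
#' @param n2o_kg cumulative N2O emission, kg N2O/ha.
#' @param ch4_kg cumulative CH4 emission, kg CH4/ha (negative = uptake).
#' @param coef GWP100 coefficients, named `n2o` and `ch4`.
#' @return kg CO2-eq/ha (vectorized).
#' @examples
#' gwp(1, 0)  # 273
#' gwp(0, 1)  # 27
#' @export
gwp <- function(n2o_kg, ch4_kg, coef = c(n2o = 273, ch4 = 27)) {
  stopifnot(all(c("n2o", "ch4") %in% names(coef)), all(coef > 0))
  n2o_kg * coef[["n2o"]] + ch4_kg * coef[["ch4"]]
}

#' Convert N2O-N mass to N2O species mass
#'
#' Field totals are customarily reported on a nitrogen basis
#' (kg N2O-N/ha); the GWP conversion needs the species mass. The factor is
#' the molar mass ratio 44/28.
#'
#' @param n2o_n_kg N2O emission as nitrogen mass (kg N/ha, >= 0).
#' @return kg N2O/ha.
#' @examples
#' n_basis_to_species(28)  # 44
#' @export
n_basis_to_species <- function(n2o_n_kg) {
  if (any(n2o_n_kg < 0, na.rm = TRUE)) {
    stop("N2O-N emission must be non-negative")
  }
  n2o_n_kg * 44 / 28
}
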