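# Experiment configuration: rotation definitions, crop economics, flux,
# soil, indicator and OTU model parameters for the synthetic generator.

default_rotations <- function() {
  wm_year <- function(y) data.frame(year_in_cycle = y,
                                    crop = c("winter_wheat", "summer_maize"),
                                    stringsAsFactors = FALSE)
  list(
    list(id = "WM", cycle_years = 1L, crops = wm_year(1L)),
    list(id = "SpWM", cycle_years = 2L,
         crops = rbind(data.frame(year_in_cycle = 1L, crop = "sweet_potato"),
                       wm_year(2L))),
    list(id = "PWM", cycle_years = 2L,
         crops = rbind(data.frame(year_in_cycle = 1L, crop = "peanut"),
                       wm_year(2L))),
    list(id = "SWM", cycle_years = 2L,
         crops = rbind(data.frame(year_in_cycle = 1L, crop = "soybean"),
                       wm_year(2L))),
    list(id = "SmWM", cycle_years = 2L,
         crops = rbind(data.frame(year_in_cycle = 1L, crop = "spring_maize"),
                       wm_year(2L))),
    list(id = "RSWM", cycle_years = 2L,
         crops = rbind(data.frame(year_in_cycle = 1L,
                                  crop = c("ryegrass", "sorghum")),
                       wm_year(2L)))
  )
}

# Per-crop agronomic and economic parameters. Yields are at commercial
# moisture (13% grain, 14% peanut pods, 30% silage moisture, fresh tubers
# for sweet potato, oven-dry for ryegrass); `moisture` supports conversion
# to a dry-matter basis. Prices/costs in Yuan, beta = protein fraction.
default_crop_table <- function() {
  data.frame(
    crop = c("winter_wheat", "summer_maize", "spring_maize", "sweet_potato",
             "peanut", "soybean", "ryegrass", "sorghum"),
    yield_mean = c(6500, 7200, 8500, 43000, 5250, 4700, 8000, 45000),
    yield_cv   = c(0.05, 0.05, 0.05, 0.06, 0.06, 0.06, 0.08, 0.08),
    price      = c(2.8, 2.6, 2.6, 1.43, 7.0, 5.8, 0.6, 0.5),
    cost       = c(12000, 11000, 10000, 30000, 18000, 7000, 3000, 9000),
    beta       = c(0.140, 0.115, 0.090, 0.015, 0.250, 0.400, 0.190, 0.026),
    moisture   = c(0.13, 0.13, 0.13, 0.70, 0.14, 0.13, 0.00, 0.30),
    stringsAsFactors = FALSE
  )
}

# Per-kg nutritional composition (a configurable subset of the components
# a full food-composition table would carry). Protein equals beta so a
# protein-only composite reduces exactly to protein yield.
default_nutrient_table <- function() {
  crops <- default_crop_table()
  data.frame(
    crop      = crops$crop,
    protein   = crops$beta,
    fat       = c(0.020, 0.040, 0.040, 0.001, 0.450, 0.200, 0.030, 0.030),
    starch    = c(0.650, 0.700, 0.700, 0.200, 0.160, 0.300, 0.450, 0.150),
    fiber     = c(0.110, 0.070, 0.070, 0.013, 0.085, 0.090, 0.250, 0.060),
    calcium   = c(3e-4, 1e-4, 1e-4, 3e-4, 5e-4, 2e-3, 5e-3, 4e-4),
    iron      = c(4e-5, 3e-5, 3e-5, 6e-6, 2e-5, 8e-5, 1e-4, 3e-5),
    vitamin_c = c(0, 0, 0, 2e-4, 0, 0, 0, 0),
    stringsAsFactors = FALSE
  )
}

default_economics <- function() {
  list(
    cpi = data.frame(year = c(2008, 2016:2022),
                     cpi = c(100, 117.0, 119.0, 121.5, 125.0,
                             128.0, 129.2, 131.8)),
    base_year = 2008,
    wheat_price = data.frame(year = 2016:2022, price = rep(2.8, 7)),
    currency = "CNY",
    usd_rate = 6.95
  )
}

default_flux <- function() {
  list(
    gases = data.frame(gas = c("n2o", "ch4"),
                       M = c(44, 16),
                       ambient_ppm = c(0.33, 1.90),
                       noise_sd_ug = c(25, 8),
                       stringsAsFactors = FALSE),
    # annual cumulative targets per rotation: N2O on an N basis (kg N/ha/yr),
    # CH4 as species mass (kg CH4/ha/yr, negative = soil sink)
    annual_n2o_kgN = c(WM = 8.9, SpWM = 4.54, PWM = 6.23,
                       SWM = 5.16, SmWM = 7.60, RSWM = 7.30),
    annual_ch4_kg = c(WM = -2.004, SpWM = -3.53, PWM = -2.67,
                      SWM = -2.94, SmWM = -2.67, RSWM = -3.00),
    pulse_fraction = 0.4,   # share of annual emission from fertilization pulses
    half_life_days = 5,     # exponential pulse decay half-life
    interval_days = 7,      # routine sampling interval
    season = c(0, 357),     # sampled window, days from the season start
    chamber = list(H_m = 0.3, P_kPa = 101.325, times_min = c(0, 12, 24, 36)),
    # fertilization days-of-season, one vector per year of the cycle
    fert_days = list(
      WM   = list(c(5, 170, 250, 285)),
      SpWM = list(c(215), c(5, 170, 250, 285)),
      PWM  = list(c(210), c(5, 170, 250, 285)),
      SWM  = list(c(210), c(5, 170, 250, 285)),
      SmWM = list(c(185, 255), c(5, 170, 250, 285)),
      RSWM = list(c(10, 200), c(5, 170, 250, 285))
    ),
    rain_days = c(280, 300) # monsoon events also trigger extra sampling
  )
}

default_soil <- function() {
  list(
    layers = data.frame(
      top_cm = c(0, 10, 20, 30, 50, 70),
      bottom_cm = c(10, 20, 30, 50, 70, 90),
      conc_2016 = c(11.50, 11.80, 7.03, 2.80, 2.13, 2.10),
      bd = c(1.49, 1.53, 1.57, 1.60, 1.62, 1.64)
    ),
    # SOC accrual rate per rotation (t C/ha/yr, ground truth for delta_soc)
    accrual = c(WM = 0.693, SpWM = 1.44, PWM = 2.03,
                SWM = 1.91, SmWM = 0.45, RSWM = 0.21),
    accrual_depth_share = c(0.40, 0.25, 0.12, 0.10, 0.07, 0.06),
    conc_noise_sd = c(0.35, 0.35, 0.25, 0.15, 0.10, 0.10),
    bd_noise_sd = 0.02
  )
}

default_indicators <- function() {
  ind <- c("BD", "SWC", "pH", "TN", "SOC", "DOC", "NO3N", "AP", "MBC", "MBN")
  mean_2016 <- c(BD = 1.49, SWC = 0.24, pH = 7.6, TN = 1.06, SOC = 11.5,
                 DOC = 180, NO3N = 15, AP = 9.3, MBC = 220, MBN = 35)
  sds <- c(BD = 0.05, SWC = 0.02, pH = 0.12, TN = 0.05, SOC = 0.40,
           DOC = 12, NO3N = 2.5, AP = 1.2, MBC = 20, MBN = 4)
  m22 <- rbind(
    WM   = c(1.53, 0.228, 7.55, 1.05, 11.8, 162, 13.5, 9.8, 200, 31),
    SpWM = c(1.43, 0.250, 7.30, 1.08, 12.7, 205, 15.0, 11.0, 260, 42),
    PWM  = c(1.40, 0.260, 7.20, 1.04, 13.0, 227, 14.0, 8.9, 290, 48),
    SWM  = c(1.42, 0.255, 7.27, 1.10, 12.8, 208, 14.5, 9.6, 270, 44),
    SmWM = c(1.50, 0.235, 7.45, 1.11, 12.3, 182, 17.0, 10.2, 235, 37),
    RSWM = c(1.47, 0.240, 7.40, 1.09, 11.9, 168, 16.0, 10.0, 300, 40)
  )
  colnames(m22) <- ind
  list(
    directions = c(BD = "less", SWC = "more", pH = "optimum", TN = "more",
                   SOC = "more", DOC = "more", NO3N = "more", AP = "more",
                   MBC = "more", MBN = "more"),
    ph_target = 7.0,
    mean_2016 = mean_2016,
    mean_2022 = m22,
    sd = sds
  )
}

default_otu <- function() {
  list(
    markers = list(
      `16S` = list(n_taxa = 800L, depth = 20000L, sdlog = 2.0),
      `ITS` = list(n_taxa = 350L, depth = 15000L, sdlog = 2.4)
    ),
    # reduction of the log-normal shape parameter in 2022 (more even
    # community = higher diversity); 0 = unchanged community
    sdlog_shift_2022 = c(WM = 0, SpWM = 0.25, PWM = 0.30,
                         SWM = 0.28, SmWM = 0.02, RSWM = 0.02),
    depth_jitter = c(0.90, 1.15)
  )
}

default_inventory <- function() {
  kinds <- c("fert_n", "fert_p2o5", "fert_k2o", "diesel_l",
             "electricity_kwh", "pesticide_kg", "seed_kg", "labor_h")
  wm <- c(550, 120, 90, 130, 2400, 9, 260, 300)
  yr1 <- list(
    SpWM = c(120, 90, 120, 100, 700, 5, 60, 400),
    PWM  = c(120, 80, 60, 90, 800, 6, 130, 350),
    SWM  = c(60, 70, 50, 80, 600, 5, 90, 250),
    SmWM = c(160, 70, 50, 80, 900, 5, 30, 180),
    RSWM = c(320, 90, 70, 110, 1500, 4, 70, 260)
  )
  rows <- list(data.frame(rotation = "WM", year_in_cycle = 1L,
                          input_kind = kinds, amount = wm,
                          stringsAsFactors = FALSE))
  for (r in names(yr1)) {
    rows[[length(rows) + 1L]] <-
      data.frame(rotation = r, year_in_cycle = 1L, input_kind = kinds,
                 amount = yr1[[r]], stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <-
      data.frame(rotation = r, year_in_cycle = 2L, input_kind = kinds,
                 amount = wm, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Default emission-factor table for agricultural inputs
#'
#' Cradle-to-farm-gate CO2-equivalent coefficients per native input unit.
#' The values are editable placeholder coefficients in the range reported
#' by published life-cycle inventories for Chinese cropping systems; they
#' are data, not code, and can be replaced with a site-specific table.
#'
#' @return A data frame with columns `input_kind`, `unit`,
#'   `kg_co2e_per_unit`.
#' @export
default_emission_factors <- function() {
  data.frame(
    input_kind = c("fert_n", "fert_p2o5", "fert_k2o", "diesel_l",
                   "electricity_kwh", "pesticide_kg", "seed_kg", "labor_h"),
    unit = c("kg N", "kg P2O5", "kg K2O", "L", "kWh", "kg a.i.", "kg", "h"),
    kg_co2e_per_unit = c(8.3, 1.51, 0.98, 3.32, 1.23, 19.1, 1.58, 0),
    stringsAsFactors = FALSE
  )
}

#' Build (and validate) an experiment configuration
#'
#' Returns the full parameter set the synthetic generator and pipeline
#' consume. The default reproduces the structure of a six-rotation,
#' three-replicate, six-year randomized complete block trial: a
#' wheat--maize double-cropping control (1-year cycle) plus five
#' diversified rotations (2-year cycles) introducing sweet potato, peanut,
#' soybean, spring maize, or a ryegrass--sorghum forage year. All group
#' means the generator draws around (flux targets, SOC accrual rates,
#' indicator means, crop economics) are recorded as ground truth for
#' parameter-recovery testing.
#'
#' @param ... named overrides. Top-level elements (`n_replicates`,
#'   `n_years`, `seed`, `rotations`, ...) are replaced; nested lists
#'   (`flux`, `soil`, `otu`, `indicators`, `economics`) are merged
#'   element-wise via [utils::modifyList()].
#' @return A validated list of class `"experiment_config"`.
#' @examples
#' cfg <- experiment_config()
#' cfg$n_replicates
#' small <- experiment_config(n_years = 2, otu = list(
#'   markers = list(`16S` = list(n_taxa = 50L, depth = 500L, sdlog = 2))))
#' @export
experiment_config <- function(...) {
  cfg <- list(
    rotations = default_rotations(),
    n_replicates = 3L,
    n_years = 6L,
    start_year = 2016L,
    seed = 20161001L,
    crops = default_crop_table(),
    carryover_gain = 1.09,
    nutrients = default_nutrient_table(),
    economics = default_economics(),
    flux = default_flux(),
    soil = default_soil(),
    indicators = default_indicators(),
    otu = default_otu(),
    inventory = default_inventory(),
    emission_factors = default_emission_factors()
  )
  over <- list(...)
  if (length(over)) {
    if (is.null(names(over)) || any(names(over) == "")) {
      stop("overrides to experiment_config() must be named", call. = FALSE)
    }
    for (nm in names(over)) {
      mergeable <- nm %in% names(cfg) &&
        is.list(cfg[[nm]]) && is.list(over[[nm]]) &&
        !is.data.frame(cfg[[nm]]) && !is.data.frame(over[[nm]]) &&
        length(over[[nm]]) > 0 && !is.null(names(over[[nm]])) &&
        all(names(over[[nm]]) != "")
      cfg[[nm]] <- if (mergeable) {
        modifyList(cfg[[nm]], over[[nm]])
      } else {
        over[[nm]]
      }
    }
    # registry-style nested lists are replaced outright, never merged,
    # so a trimmed override does not inherit leftover default entries
    if (!is.null(over$otu$markers)) cfg$otu$markers <- over$otu$markers
    if (!is.null(over$flux$fert_days)) cfg$flux$fert_days <- over$flux$fert_days
  }
  class(cfg) <- "experiment_config"
  validate_config(cfg)
  cfg
}

#' Validate an experiment configuration
#'
#' Checks the structural invariants the generator relies on and fails with
#' an error naming the offending field.
#'
#' @param cfg a list of class `"experiment_config"`.
#' @return `cfg`, invisibly, if valid.
#' @export
validate_config <- function(cfg) {
  fail <- function(field, msg) {
    stop(sprintf("invalid configuration [%s]: %s", field, msg), call. = FALSE)
  }
  if (cfg$n_replicates < 2) fail("n_replicates", "must be >= 2")
  if (cfg$n_years < 1) fail("n_years", "must be >= 1")
  ids <- vapply(cfg$rotations, `[[`, "", "id")
  if (anyDuplicated(ids)) fail("rotations", "duplicated rotation ids")
  cyc <- vapply(cfg$rotations, `[[`, 0, "cycle_years")
  if (any(cyc > cfg$n_years)) {
    fail("rotations", sprintf("cycle of %s longer than n_years",
                              paste(ids[cyc > cfg$n_years], collapse = ", ")))
  }
  for (r in cfg$rotations) {
    miss <- setdiff(r$crops$crop, cfg$crops$crop)
    if (length(miss)) {
      fail("crops", sprintf("rotation %s uses crops missing from the crop table: %s",
                            r$id, paste(miss, collapse = ", ")))
    }
  }
  with(cfg$crops, {
    if (any(yield_mean < 0)) fail("crops$yield_mean", "negative yield mean")
    if (any(yield_cv < 0)) fail("crops$yield_cv", "negative yield CV")
    if (any(price < 0) || any(cost < 0)) fail("crops", "negative price or cost")
    if (any(beta < 0 | beta > 1)) fail("crops$beta", "protein fraction outside [0, 1]")
  })
  if (any(cfg$economics$cpi$cpi <= 0)) fail("economics$cpi", "CPI must be > 0")
  if (!cfg$economics$base_year %in% cfg$economics$cpi$year) {
    fail("economics$base_year", "base year missing from the CPI series")
  }
  if (any(cfg$flux$gases$noise_sd_ug < 0)) fail("flux$gases$noise_sd_ug", "negative SD")
  if (cfg$flux$pulse_fraction < 0 || cfg$flux$pulse_fraction >= 1) {
    fail("flux$pulse_fraction", "must be in [0, 1)")
  }
  if (cfg$flux$half_life_days <= 0) fail("flux$half_life_days", "must be > 0")
  for (r in ids) {
    if (is.null(cfg$flux$fert_days[[r]])) {
      fail("flux$fert_days", sprintf("no fertilization calendar for rotation %s", r))
    }
  }
  if (any(cfg$soil$conc_noise_sd < 0)) fail("soil$conc_noise_sd", "negative SD")
  if (cfg$soil$bd_noise_sd < 0) fail("soil$bd_noise_sd", "negative SD")
  lay <- cfg$soil$layers
  if (any(diff(lay$top_cm) <= 0) || any(lay$bottom_cm <= lay$top_cm) ||
      any(lay$top_cm[-1] != lay$bottom_cm[-nrow(lay)])) {
    fail("soil$layers", "layers must be contiguous, non-overlapping and increasing")
  }
  if (abs(sum(cfg$soil$accrual_depth_share) - 1) > 1e-8) {
    fail("soil$accrual_depth_share", "depth shares must sum to 1")
  }
  if (any(cfg$indicators$sd <= 0)) fail("indicators$sd", "SDs must be > 0")
  for (m in names(cfg$otu$markers)) {
    mk <- cfg$otu$markers[[m]]
    if (mk$n_taxa < 2) fail(sprintf("otu$markers$%s$n_taxa", m), "must be >= 2")
    if (mk$depth < 1) fail(sprintf("otu$markers$%s$depth", m), "must be >= 1")
    if (mk$sdlog < 0) fail(sprintf("otu$markers$%s$sdlog", m), "negative shape")
  }
  missing_ef <- setdiff(cfg$inventory$input_kind,
                        cfg$emission_factors$input_kind)
  if (length(missing_ef)) {
    fail("emission_factors",
         sprintf("no factor for input kind(s): %s",
                 paste(unique(missing_ef), collapse = ", ")))
  }
  invisible(cfg)
}

# md5 digest of a configuration (serialized to a temporary file); used to
# stamp every derived output for provenance.
hash_config <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(cfg, f, version = 2)
  unname(tools::md5sum(f))
}
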