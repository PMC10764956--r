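# Synthetic experiment generator: a seeded randomized complete block
# rotation trial with crop records, chamber flux series, layered soil
# profiles, soil indicator tables and OTU tables, plus the generating
# parameters as recoverable ground truth.

#' Generate one plot-gas chamber flux series
#'
#' Builds the weekly static-chamber sampling schedule for one season
#' (extra deployments 1 and 3 days after every fertilization event and
#' 1 day after rain events), draws the noise-free flux profile
#' `baseline + sum of exponentially decaying fertilization pulses`, adds
#' Gaussian noise on the closure slope, and expands each deployment into
#' a linear headspace concentration series at the configured closure
#' times. Slopes are truncated so concentrations never go negative.
#'
#' When `target_annual_kg` is supplied, the noise-free profile is scaled
#' so that its trapezoidal integral over the sampled dates equals the
#' target exactly; the expected cumulative emission recovered downstream
#' then equals the configured ground truth with no discretization bias.
#'
#' @param plot plot identifier.
#' @param calendar list with `start`, `end` (days), `fert_days`, and
#'   optionally `rain_days` (days on the same scale).
#' @param gas `"n2o"` or `"ch4"`.
#' @param params list: `baseline` and `pulse_amplitude`
#'   (ug m^-2 h^-1 unless `target_annual_kg` rescales the profile),
#'   `half_life_days`, `noise_sd` (ug m^-2 h^-1), `ambient_ppm`,
#'   optional `target_annual_kg` (kg/ha over the season, species mass),
#'   `interval_days` (default 7), and `chamber` (`H_m`, `P_kPa`,
#'   `times_min`).
#' @param seed integer seed for the slope noise.
#' @param start_date optional `Date` mapped to day 0.
#' @return A chamber-format data frame (`plot`, `gas`, `date`, `day`,
#'   `t_min`, `conc_ppm`, `T_K`, `P_kPa`, `H_m`) with attribute
#'   `"truth"`: per-date noise-free and realized fluxes.
#' @export
generate_flux_series <- function(plot, calendar, gas = c("n2o", "ch4"),
                                 params, seed = 1L, start_date = NULL) {
  gas <- match.arg(gas)
  if (is.null(calendar) || !length(calendar) ||
      is.null(calendar$start) || is.null(calendar$end)) {
    stop("empty management calendar: start/end and event dates are required")
  }
  if (is.null(calendar$fert_days)) {
    stop("management calendar must supply fertilization dates (possibly none)")
  }
  interval <- if (is.null(params$interval_days)) 7 else params$interval_days
  days <- seq(calendar$start, calendar$end, by = interval)
  extra <- c(outer(calendar$fert_days, c(1, 3), `+`),
             if (!is.null(calendar$rain_days)) calendar$rain_days + 1)
  extra <- extra[extra >= calendar$start & extra <= calendar$end]
  days <- sort(unique(c(days, extra)))
  lambda <- log(2) / params$half_life_days
  shape <- rep(params$baseline, length(days))
  for (fd in calendar$fert_days) {
    on <- days >= fd
    shape[on] <- shape[on] + params$pulse_amplitude * exp(-lambda * (days[on] - fd))
  }
  if (!is.null(params$target_annual_kg)) {
    area <- sum((shape[-1] + shape[-length(shape)]) / 2 * diff(days))
    if (area == 0) stop("flux profile integrates to zero; cannot scale to target")
    # scale so trapz(flux kg/ha/h, days) * 24 == target
    flux_ug <- shape * params$target_annual_kg / (area * 1e-5 * 24)
  } else {
    flux_ug <- shape
  }
  flux_real <- with_stream_seed(seed, paste("fluxnoise", plot, gas), {
    flux_ug + rnorm(length(days), 0, params$noise_sd)
  })
  cst <- flux_constants()
  ch <- params$chamber
  t_k <- 287.5 + 11 * sin(2 * pi * ((days %% 365) - 190) / 365)
  k <- cst$M[[gas]] / cst$V0 * (cst$T0 / t_k) * (ch$P_kPa / cst$P0) *
    ch$H_m * 60
  slope <- flux_real / k
  # keep headspace concentrations physical over the closure
  slope_min <- -(params$ambient_ppm - 1e-3) / max(ch$times_min)
  slope <- pmax(slope, slope_min)
  nt <- length(ch$times_min)
  out <- data.frame(
    plot = plot, gas = gas,
    day = rep(days, each = nt),
    t_min = rep(ch$times_min, length(days)),
    conc_ppm = params$ambient_ppm + rep(slope, each = nt) *
      rep(ch$times_min, length(days)),
    T_K = rep(t_k, each = nt),
    P_kPa = ch$P_kPa, H_m = ch$H_m,
    stringsAsFactors = FALSE
  )
  out$date <- if (is.null(start_date)) out$day else start_date + out$day
  attr(out, "truth") <- data.frame(day = days, flux_ug_true = flux_ug,
                                   flux_ug_realized = slope * k)
  out
}

# rotation lookup helpers
rotation_ids <- function(cfg) vapply(cfg$rotations, `[[`, "", "id")
rotation_by_id <- function(cfg, id) {
  cfg$rotations[[match(id, rotation_ids(cfg))]]
}

generate_design <- function(cfg) {
  ids <- rotation_ids(cfg)
  with_stream_seed(cfg$seed, "design", {
    rot <- unlist(lapply(seq_len(cfg$n_replicates),
                         function(b) sample(ids)))
    data.frame(
      plot = sprintf("P%02d", seq_along(rot)),
      block = rep(seq_len(cfg$n_replicates), each = length(ids)),
      rotation = rot,
      stringsAsFactors = FALSE
    )
  })
}

generate_crop_records <- function(cfg, plots, block_effects) {
  crops <- cfg$crops
  wheat_price <- cfg$economics$wheat_price
  rows <- list()
  for (i in seq_len(nrow(plots))) {
    p <- plots[i, ]
    rot <- rotation_by_id(cfg, p$rotation)
    for (y in seq_len(cfg$n_years)) {
      yic <- ((y - 1L) %% rot$cycle_years) + 1L
      season <- rot$crops[rot$crops$year_in_cycle == yic, , drop = FALSE]
      for (cr in season$crop) {
        cp <- crops[crops$crop == cr, ]
        carry <- if (rot$cycle_years > 1 &&
                     cr %in% c("winter_wheat", "summer_maize")) {
          cfg$carryover_gain
        } else 1
        mu <- cp$yield_mean * carry * (1 + block_effects[p$block])
        yld <- with_stream_seed(cfg$seed,
                                paste("crops", p$plot, y, cr), {
          max(0, mu * (1 + rnorm(1, 0, cp$yield_cv)))
        })
        cal_year <- cfg$start_year + y  # harvested the year after sowing starts
        wp <- wheat_price$price[match(cal_year, wheat_price$year)]
        if (is.na(wp)) wp <- wheat_price$price[nrow(wheat_price)]
        rows[[length(rows) + 1L]] <- data.frame(
          plot = p$plot, block = p$block, rotation = p$rotation,
          year = cal_year, year_index = y, year_in_cycle = yic, crop = cr,
          yield_kg_ha = yld, price = cp$price, wheat_price = wp,
          cost = cp$cost, beta = cp$beta, moisture = cp$moisture,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

generate_chamber_data <- function(cfg, plots) {
  fx <- cfg$flux
  start_date <- as.Date(sprintf("%d-10-01", cfg$start_year))
  out <- vector("list", nrow(plots) * nrow(fx$gases) * cfg$n_years)
  n <- 0L
  for (i in seq_len(nrow(plots))) {
    p <- plots[i, ]
    rot <- rotation_by_id(cfg, p$rotation)
    fert_by_year <- fx$fert_days[[p$rotation]]
    for (g in seq_len(nrow(fx$gases))) {
      gas <- fx$gases$gas[g]
      target <- if (gas == "n2o") {
        fx$annual_n2o_kgN[[p$rotation]] * 44 / 28  # N basis -> species mass
      } else {
        fx$annual_ch4_kg[[p$rotation]]
      }
      for (y in seq_len(cfg$n_years)) {
        yic <- ((y - 1L) %% rot$cycle_years) + 1L
        offset <- (y - 1L) * 365
        fert <- fert_by_year[[min(yic, length(fert_by_year))]] + offset
        calendar <- list(start = fx$season[1] + offset,
                         end = fx$season[2] + offset,
                         fert_days = fert,
                         rain_days = fx$rain_days + offset)
        n_f <- length(fert)
        span <- diff(fx$season)
        amp <- if (n_f > 0 && fx$pulse_fraction > 0) {
          fx$pulse_fraction * span * (log(2) / fx$half_life_days) /
            ((1 - fx$pulse_fraction) * n_f)
        } else 0
        params <- list(baseline = 1, pulse_amplitude = amp,
                       half_life_days = fx$half_life_days,
                       noise_sd = fx$gases$noise_sd_ug[g],
                       ambient_ppm = fx$gases$ambient_ppm[g],
                       target_annual_kg = target,
                       interval_days = fx$interval_days,
                       chamber = fx$chamber)
        ser <- generate_flux_series(p$plot, calendar, gas, params,
                                    seed = child_seed(cfg$seed,
                                                      paste("flux", p$plot, gas, y)),
                                    start_date = start_date)
        ser$rotation <- p$rotation
        ser$year <- y
        n <- n + 1L
        out[[n]] <- ser
      }
    }
  }
  res <- do.call(rbind, out[seq_len(n)])
  rownames(res) <- NULL
  res
}

generate_soil_profiles <- function(cfg, plots) {
  so <- cfg$soil
  lay <- so$layers
  thick <- lay$bottom_cm - lay$top_cm
  rows <- list()
  for (i in seq_len(nrow(plots))) {
    p <- plots[i, ]
    accr <- so$accrual[[p$rotation]]
    # concentration increment per layer placing accrual*n_years t C/ha
    # into the profile along the configured depth shares
    d_conc <- accr * cfg$n_years * so$accrual_depth_share /
      (lay$bd * thick * 0.1)
    draws <- with_stream_seed(cfg$seed, paste("soil", p$plot), {
      list(c16 = lay$conc_2016 + rnorm(nrow(lay), 0, so$conc_noise_sd),
           c22 = lay$conc_2016 + d_conc + rnorm(nrow(lay), 0, so$conc_noise_sd),
           b16 = lay$bd + rnorm(nrow(lay), 0, so$bd_noise_sd),
           b22 = lay$bd + rnorm(nrow(lay), 0, so$bd_noise_sd))
    })
    for (tp in c("2016", "2022")) {
      rows[[length(rows) + 1L]] <- data.frame(
        plot = p$plot, rotation = p$rotation, timepoint = as.integer(tp),
        top_cm = lay$top_cm, bottom_cm = lay$bottom_cm,
        soc_g_kg = pmax(0.05, if (tp == "2016") draws$c16 else draws$c22),
        bd_g_cm3 = pmax(0.8, if (tp == "2016") draws$b16 else draws$b22),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

generate_indicator_table <- function(cfg, plots) {
  ind <- cfg$indicators
  ind_names <- names(ind$mean_2016)
  rows <- list()
  for (i in seq_len(nrow(plots))) {
    p <- plots[i, ]
    for (tp in c(2016L, 2022L)) {
      mu <- if (tp == 2016L) ind$mean_2016 else ind$mean_2022[p$rotation, ]
      vals <- with_stream_seed(cfg$seed,
                               paste("indicators", p$plot, tp), {
        as.numeric(mu) + rnorm(length(ind_names), 0, as.numeric(ind$sd))
      })
      rows[[length(rows) + 1L]] <- data.frame(
        plot = p$plot, rotation = p$rotation, block = p$block,
        timepoint = tp, indicator = ind_names, value = vals,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# deterministic community profile: evenly spaced log-normal quantiles,
# so the population Shannon index is an exact function of the shape
lognormal_profile <- function(n_taxa, sdlog) {
  q <- stats::qlnorm((seq_len(n_taxa) - 0.5) / n_taxa, meanlog = 0,
                     sdlog = sdlog)
  q / sum(q)
}

generate_otu_tables <- function(cfg, plots) {
  out <- list()
  truth <- list()
  for (m in names(cfg$otu$markers)) {
    mk <- cfg$otu$markers[[m]]
    samples <- expand.grid(plot = plots$plot, timepoint = c(2016L, 2022L),
                           stringsAsFactors = FALSE)
    samples$rotation <- plots$rotation[match(samples$plot, plots$plot)]
    samples$sample <- paste(samples$plot, samples$timepoint, sep = "_")
    counts <- matrix(0L, nrow = mk$n_taxa, ncol = nrow(samples),
                     dimnames = list(sprintf("OTU%04d", seq_len(mk$n_taxa)),
                                     samples$sample))
    for (s in seq_len(nrow(samples))) {
      shift <- if (samples$timepoint[s] == 2022L) {
        cfg$otu$sdlog_shift_2022[[samples$rotation[s]]]
      } else 0
      p <- lognormal_profile(mk$n_taxa, mk$sdlog - shift)
      counts[, s] <- with_stream_seed(cfg$seed,
                                      paste("otu", m, samples$sample[s]), {
        depth <- round(mk$depth * runif(1, cfg$otu$depth_jitter[1],
                                        cfg$otu$depth_jitter[2]))
        as.integer(rmultinom(1, depth, p))
      })
    }
    out[[m]] <- list(counts = counts, meta = samples, marker = m)
    sh <- expand.grid(rotation = rotation_ids(cfg),
                      timepoint = c(2016L, 2022L), stringsAsFactors = FALSE)
    sh$shannon <- vapply(seq_len(nrow(sh)), function(k) {
      shift <- if (sh$timepoint[k] == 2022L) {
        cfg$otu$sdlog_shift_2022[[sh$rotation[k]]]
      } else 0
      p <- lognormal_profile(mk$n_taxa, mk$sdlog - shift)
      -sum(p * log(p))
    }, 0)
    sh$marker <- m
    truth[[m]] <- sh
  }
  attr(out, "population_shannon") <- do.call(rbind, truth)
  out
}

#' Generate a complete synthetic rotation experiment
#'
#' Produces every data stream the assessment pipeline consumes -- plot
#' layout, crop records, chamber gas series, two-timepoint layered soil
#' profiles, a 10-indicator soil table, OTU tables for two gene markers,
#' input inventories -- with the statistical structure of a randomized
#' complete block trial. All group-level expectations equal the
#' configured ground truth (stored in `$ground_truth`), and identical
#' seeds give bit-identical datasets.
#'
#' @param config an [experiment_config()].
#' @param streams which streams to generate (subset of `"crops"`,
#'   `"flux"`, `"soil"`, `"indicators"`, `"otu"`); trimming streams
#'   speeds up targeted simulation studies.
#' @return A list of class `"rotation_dataset"`: `plots`,
#'   `crop_records`, `chamber`, `soil_profiles`, `indicators`, `otu`,
#'   `inventory`, `emission_factors`, `ground_truth`, `config`.
#' @examples
#' cfg <- experiment_config()
#' ds <- generate_dataset(cfg, streams = "crops")
#' nrow(ds$plots)  # 18
#' @export
generate_dataset <- function(config = experiment_config(),
                             streams = c("crops", "flux", "soil",
                                         "indicators", "otu")) {
  validate_config(config)
  streams <- match.arg(streams, several.ok = TRUE)
  plots <- generate_design(config)
  block_effects <- with_stream_seed(config$seed, "blocks", {
    rnorm(config$n_replicates, 0, 0.03)
  })
  ds <- list(plots = plots, config = config)
  if ("crops" %in% streams) {
    ds$crop_records <- generate_crop_records(config, plots, block_effects)
  }
  if ("flux" %in% streams) {
    ds$chamber <- generate_chamber_data(config, plots)
  }
  if ("soil" %in% streams) {
    ds$soil_profiles <- generate_soil_profiles(config, plots)
  }
  if ("indicators" %in% streams) {
    ds$indicators <- generate_indicator_table(config, plots)
  }
  if ("otu" %in% streams) {
    ds$otu <- generate_otu_tables(config, plots)
  }
  ds$inventory <- config$inventory
  ds$emission_factors <- config$emission_factors
  ds$ground_truth <- list(
    block_effects = block_effects,
    flux_annual_n2o_kgN = config$flux$annual_n2o_kgN,
    flux_annual_ch4_kg = config$flux$annual_ch4_kg,
    soc_accrual_t_c_ha_yr = config$soil$accrual,
    indicator_means = config$indicators[c("mean_2016", "mean_2022")],
    crop_yield_means = config$crops[, c("crop", "yield_mean")],
    population_shannon = if (!is.null(ds$otu)) {
      attr(ds$otu, "population_shannon")
    }
  )
  class(ds) <- "rotation_dataset"
  ds
}

#' @export
print.rotation_dataset <- function(x, ...) {
  cat("<rotation_dataset>\n")
  cat(sprintf("  %d plots, %d rotations, %d blocks, %d years\n",
              nrow(x$plots), length(unique(x$plots$rotation)),
              length(unique(x$plots$block)), x$config$n_years))
  for (nm in c("crop_records", "chamber", "soil_profiles", "indicators")) {
    if (!is.null(x[[nm]])) cat(sprintf("  %s: %d rows\n", nm, nrow(x[[nm]])))
  }
  if (!is.null(x$otu)) {
    for (m in setdiff(names(x$otu), "population_shannon")) {
      cat(sprintf("  otu %s: %d taxa x %d samples\n", m,
                  nrow(x$otu[[m]]$counts), ncol(x$otu[[m]]$counts)))
    }
  }
  invisible(x)
}

#' Write a dataset to a directory of plain-text tables
#'
#' One CSV per tabular stream, OTU tables as taxa x samples TSV with a
#' leading taxon-id column, and a JSON manifest echoing the configuration
#' (with its md5 hash and seed) for provenance.
#'
#' @param dataset a `"rotation_dataset"`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "rotation_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  wr <- function(df, name) {
    f <- file.path(dir, name)
    write.csv(df, f, row.names = FALSE)
    paths[[length(paths) + 1L]] <<- f
  }
  wr(dataset$plots, "plots.csv")
  for (nm in c("crop_records", "chamber", "soil_profiles", "indicators",
               "inventory", "emission_factors")) {
    if (!is.null(dataset[[nm]])) wr(dataset[[nm]], paste0(nm, ".csv"))
  }
  if (!is.null(dataset$otu)) {
    for (m in setdiff(names(dataset$otu), "population_shannon")) {
      tab <- dataset$otu[[m]]
      f <- file.path(dir, sprintf("otu_%s.tsv", gsub("[^A-Za-z0-9]", "", m)))
      out <- data.frame(taxon_id = rownames(tab$counts), tab$counts,
                        check.names = FALSE)
      utils::write.table(out, f, sep = "\t", row.names = FALSE, quote = FALSE)
      paths[[length(paths) + 1L]] <- f
      wr(tab$meta, sprintf("otu_%s_meta.csv", gsub("[^A-Za-z0-9]", "", m)))
    }
  }
  manifest <- list(
    package = "rotimpact",
    config_hash = hash_config(dataset$config),
    seed = dataset$config$seed,
    n_plots = nrow(dataset$plots),
    files = basename(unlist(paths))
  )
  mf <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(unlist(paths), mf))
}
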