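# Synthetic experiment generator: design, determinism, flux model,
# parameter recovery.

test_that("default design is a balanced randomized complete block trial", {
  ds <- generate_dataset(experiment_config(), streams = "crops")
  expect_equal(nrow(ds$plots), 18)
  # each rotation replicated once per block
  tab <- table(ds$plots$rotation, ds$plots$block)
  expect_true(all(tab == 1))
  expect_equal(as.vector(table(ds$plots$rotation)), rep(3L, 6))
  # every plot in exactly one rotation and block
  expect_false(anyDuplicated(ds$plots$plot) > 0)
})

test_that("equal seeds give bit-identical datasets, different seeds differ", {
  cfg <- experiment_config(n_years = 2L, otu = list(markers = list(
    `16S` = list(n_taxa = 40L, depth = 400L, sdlog = 1.5))))
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$crop_records, d2$crop_records)
  expect_identical(d1$chamber, d2$chamber)
  expect_identical(d1$soil_profiles, d2$soil_profiles)
  expect_identical(d1$indicators, d2$indicators)
  expect_identical(d1$otu$`16S`$counts, d2$otu$`16S`$counts)
  cfg2 <- experiment_config(n_years = 2L, seed = 99L, otu = list(markers = list(
    `16S` = list(n_taxa = 40L, depth = 400L, sdlog = 1.5))))
  d3 <- generate_dataset(cfg2)
  expect_false(identical(d1$crop_records$yield_kg_ha,
                         d3$crop_records$yield_kg_ha))
})

test_that("configuration errors name the offending field", {
  expect_error(experiment_config(n_replicates = 1L), "n_replicates")
  expect_error(experiment_config(n_years = 1L), "cycle")
  expect_error(experiment_config(soil = list(conc_noise_sd = c(-1, rep(0.1, 5)))),
               "conc_noise_sd")
  expect_error(experiment_config(flux = list(pulse_fraction = 1.2)),
               "pulse_fraction")
  bad_crops <- default_crop_table()
  bad_crops$beta[1] <- 1.4
  expect_error(experiment_config(crops = bad_crops), "beta")
})

test_that("flux series follow the configured pulse model", {
  calendar <- list(start = 0, end = 100, fert_days = c(30), rain_days = 60)
  chamber <- list(H_m = 0.3, P_kPa = 101.325, times_min = c(0, 12, 24, 36))
  # null model: zero baseline, pulses and noise give flat concentrations
  null <- generate_flux_series("P1", calendar, "n2o",
                               params = list(baseline = 0, pulse_amplitude = 0,
                                             half_life_days = 5, noise_sd = 0,
                                             ambient_ppm = 0.33,
                                             chamber = chamber), seed = 1)
  expect_true(all(null$conc_ppm == 0.33))
  # a strong pulse puts the maximum flux in the post-fertilization window
  pulsed <- generate_flux_series("P1", calendar, "n2o",
                                 params = list(baseline = 10,
                                               pulse_amplitude = 100,
                                               half_life_days = 5, noise_sd = 0,
                                               ambient_ppm = 0.33,
                                               chamber = chamber), seed = 1)
  truth <- attr(pulsed, "truth")
  peak_day <- truth$day[which.max(truth$flux_ug_true)]
  expect_true(peak_day >= 30 && peak_day <= 33)
  # sampling densifies after fertilization and dates strictly increase
  expect_true(all(c(31, 33) %in% truth$day))
  expect_true(all(diff(truth$day) > 0))
  expect_error(generate_flux_series("P1", list(), "n2o",
                                    params = list(), seed = 1), "empty")
})

test_that("generated streams satisfy their structural invariants", {
  cfg <- experiment_config(n_years = 2L, otu = list(markers = list(
    `16S` = list(n_taxa = 60L, depth = 600L, sdlog = 1.8))))
  ds <- generate_dataset(cfg)
  # flux dates strictly increasing within each plot-gas series
  key <- paste(ds$chamber$plot, ds$chamber$gas)
  for (k in unique(key)) {
    d <- unique(ds$chamber$day[key == k])
    expect_true(all(diff(d) > 0))
  }
  # OTU counts are non-negative integers
  cts <- ds$otu$`16S`$counts
  expect_true(all(cts >= 0))
  expect_identical(storage.mode(cts), "integer")
  # soil profiles contiguous per plot-timepoint
  prof <- ds$soil_profiles[ds$soil_profiles$plot == ds$plots$plot[1] &
                             ds$soil_profiles$timepoint == 2016, ]
  expect_equal(prof$top_cm[-1], prof$bottom_cm[-nrow(prof)])
})

test_that("configured SOC accrual is recovered by delta_soc across seeds", {
  # accrual 2.0 vs 0.5 t C/ha/yr, layer noise SD 0.1 g/kg, 50 seeds
  rates <- matrix(NA_real_, 50, 2, dimnames = list(NULL, c("A", "B")))
  for (s in seq_len(50)) {
    cfg <- two_rotation_config(seed = s)
    ds <- generate_dataset(cfg, streams = "soil")
    for (r in c("A", "B")) {
      plots <- ds$plots$plot[ds$plots$rotation == r]
      rr <- vapply(plots, function(p) {
        p16 <- ds$soil_profiles[ds$soil_profiles$plot == p &
                                  ds$soil_profiles$timepoint == 2016, ]
        p22 <- ds$soil_profiles[ds$soil_profiles$plot == p &
                                  ds$soil_profiles$timepoint == 2022, ]
        delta_soc(as.numeric(soc_stock(p16)), as.numeric(soc_stock(p22)),
                  cfg$n_years)$rate_t_c_ha_yr
      }, 0)
      rates[s, r] <- mean(rr)
    }
  }
  for (r in c("A", "B")) {
    est <- mean(rates[, r])
    se <- sd(rates[, r]) / sqrt(nrow(rates))
    truth <- c(A = 2.0, B = 0.5)[[r]]
    expect_lt(abs(est - truth), 3 * se)
  }
})

test_that("a dataset round-trips to a directory of plain-text tables", {
  cfg <- experiment_config(n_years = 2L, otu = list(markers = list(
    `16S` = list(n_taxa = 30L, depth = 300L, sdlog = 1.5))))
  ds <- generate_dataset(cfg)
  dir <- tempfile("dataset")
  paths <- write_dataset(ds, dir)
  expect_true(all(file.exists(paths)))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(man$n_plots, nrow(ds$plots))
  reread <- read.csv(file.path(dir, "crop_records.csv"))
  expect_equal(nrow(reread), nrow(ds$crop_records))
  otu <- read.delim(file.path(dir, "otu_16S.tsv"), check.names = FALSE)
  expect_equal(names(otu)[1], "taxon_id")
  expect_equal(unname(as.matrix(otu[, -1])), unname(ds$otu$`16S`$counts))
})
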