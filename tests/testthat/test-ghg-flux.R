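# Chamber flux fitting, trapezoidal integration and CO2-equivalents.

test_that("chamber flux matches hand evaluation of the ideal-gas scaling", {
  # slope 0.001 ppm/min at 298.15 K, ambient pressure, 0.3 m chamber
  fit <- fit_flux(c(0, 12, 24, 36), c(0.320, 0.332, 0.344, 0.356),
                  T_K = 298.15, P_kPa = 101.325, H_m = 0.3, gas = "n2o")
  expect_equal(fit$slope_ppm_min, 0.001, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$flux_ug_m2_h, 32.372, tolerance = 1e-3)
  expect_equal(fit$flux_kg_ha_h, fit$flux_ug_m2_h * 1e-5)

  # CH4 uptake: negative slope gives a negative (sink) flux
  ch4 <- fit_flux(c(0, 12, 24, 36), 1.9 - 0.0005 * c(0, 12, 24, 36),
                  T_K = 298.15, P_kPa = 101.325, H_m = 0.3, gas = "ch4")
  expect_equal(ch4$flux_ug_m2_h, -5.886, tolerance = 1e-3)
})

test_that("flux fitting handles null and invalid series", {
  flat <- fit_flux(c(0, 12, 24, 36), rep(0.33, 4), 298, 101.325, 0.3, "n2o")
  expect_equal(flat$flux_ug_m2_h, 0)
  expect_error(fit_flux(c(0, 12), c(0.3, 0.4), 298, 101, 0.3, "n2o"),
               "3 time points")
  expect_error(fit_flux(c(0, 12, 12, 36), c(0.3, 0.31, 0.32, 0.33),
                        298, 101, 0.3, "n2o"), "strictly increasing")
  expect_error(fit_flux(c(0, 12, 24), c(0.3, 0.31, 0.32), -1, 101, 0.3, "n2o"),
               "positive")
})

test_that("flux is dimensionally sound in H, T and P", {
  t <- c(0, 12, 24, 36)
  conc <- 0.33 + 0.002 * t
  base <- fit_flux(t, conc, 300, 101.325, 0.3, "n2o")
  dblH <- fit_flux(t, conc, 300, 101.325, 0.6, "n2o")
  expect_equal(dblH$flux_ug_m2_h, 2 * base$flux_ug_m2_h)
  # at the reference state the scaling reduces to (M/V0) * H * slope * 60
  cst <- flux_constants()
  ref <- fit_flux(t, conc, cst$T0, cst$P0, 0.3, "n2o")
  expect_equal(ref$flux_ug_m2_h, cst$M[["n2o"]] / cst$V0 * 0.3 * 0.002 * 60,
               tolerance = 1e-10)
})

test_that("vectorized table fitting agrees with per-series fits", {
  set.seed(7)
  rows <- list()
  for (p in c("P1", "P2")) {
    for (g in c("n2o", "ch4")) {
      for (d in c(1, 8)) {
        t <- c(0, 12, 24, 36)
        conc <- runif(1, 0.3, 2) + rnorm(1, 0, 0.002) * t + rnorm(4, 0, 1e-4)
        rows[[length(rows) + 1]] <- data.frame(
          plot = p, gas = g, date = d, t_min = t, conc_ppm = conc,
          T_K = 290 + d, P_kPa = 101, H_m = 0.3)
      }
    }
  }
  tab <- do.call(rbind, rows)
  fitted <- fit_flux_table(tab)
  expect_equal(nrow(fitted), 8)
  for (i in seq_len(nrow(fitted))) {
    sub <- tab[tab$plot == fitted$plot[i] & tab$gas == fitted$gas[i] &
                 tab$date == fitted$date[i], ]
    single <- fit_flux(sub$t_min, sub$conc_ppm, sub$T_K[1], sub$P_kPa[1],
                       sub$H_m[1], gas = fitted$gas[i])
    expect_equal(fitted$flux_ug_m2_h[i], single$flux_ug_m2_h,
                 tolerance = 1e-10)
    expect_equal(fitted$r_squared[i], single$r_squared, tolerance = 1e-10)
  }
})

test_that("cumulative emission reproduces hand trapezoids", {
  # constant 1e-4 kg/ha/h for 7 days: 1e-4 * 7 * 24
  expect_equal(cumulative_emission(c(0, 7), c(1e-4, 1e-4)), 0.0168,
               tolerance = 1e-12)
  # ramp 0 -> 0.002 over one day: mean 0.001 * 24
  expect_equal(cumulative_emission(c(0, 1), c(0, 0.002)), 0.024,
               tolerance = 1e-12)
  expect_equal(cumulative_emission(c(0, 3, 9), c(0, 0, 0)), 0)
  expect_error(cumulative_emission(c(3, 1), c(1, 2)), "strictly increasing")
  expect_error(cumulative_emission(5, 1), "at least 2")
})

test_that("trapezoid equals fine-grid integration of the interpolant", {
  set.seed(11)
  for (k in 1:5) {
    n <- sample(5:40, 1)
    days <- sort(runif(n, 0, 200))
    flux <- rnorm(n, 1e-4, 5e-5)
    got <- cumulative_emission(days, flux)
    want <- oracle_integrate(days, flux)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("window clipping interpolates onto the series boundaries", {
  days <- c(0, 10)
  flux <- c(0, 0.001)
  full <- cumulative_emission(days, flux)
  first_half <- cumulative_emission(days, flux, from = 0, to = 5)
  second_half <- cumulative_emission(days, flux, from = 5, to = 10)
  expect_equal(first_half + second_half, full, tolerance = 1e-12)
  expect_equal(first_half, 0.00025 * 5 * 24, tolerance = 1e-12)
})

test_that("GWP coefficients, linearity and the N-basis conversion hold", {
  expect_identical(gwp(1, 0), 273)
  expect_identical(gwp(0, 1), 27)
  set.seed(3)
  a <- rnorm(2); b <- rnorm(2)
  expect_equal(gwp(a[1] + b[1], a[2] + b[2]),
               gwp(a[1], a[2]) + gwp(b[1], b[2]), tolerance = 1e-12)
  expect_equal(n_basis_to_species(28), 44)
  expect_equal(n_basis_to_species(0), 0)
  expect_equal(n_basis_to_species(8.9), 8.9 * 44 / 28)
  expect_error(n_basis_to_species(-1), "non-negative")
})
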