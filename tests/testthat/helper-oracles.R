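# Independent brute-force oracles, written with literal loops and kept
# deliberately separate from the package implementation.

# Entropy-weighted TOPSIS, step by step: min-max normalization with
# direction flags, column proportions with the zero-shift rule, entropy
# over alternatives, weights, weighted matrix, ideal vectors, Euclidean
# distances and closeness coefficients.
oracle_cei <- function(x, directions) {
  x <- as.matrix(x)
  n <- nrow(x)
  m <- ncol(x)
  b <- matrix(0, n, m, dimnames = dimnames(x))
  for (j in 1:m) {
    xmin <- min(x[, j]); xmax <- max(x[, j])
    for (i in 1:n) {
      b[i, j] <- if (directions[j] == "positive") {
        (x[i, j] - xmin) / (xmax - xmin)
      } else {
        (xmax - x[i, j]) / (xmax - xmin)
      }
    }
  }
  f <- matrix(0, n, m)
  for (j in 1:m) {
    has_zero <- FALSE
    for (i in 1:n) if (b[i, j] == 0) has_zero <- TRUE
    tot <- 0
    for (i in 1:n) tot <- tot + (if (has_zero) 1 + b[i, j] else b[i, j])
    for (i in 1:n) f[i, j] <- (if (has_zero) 1 + b[i, j] else b[i, j]) / tot
  }
  H <- numeric(m)
  for (j in 1:m) {
    s <- 0
    for (i in 1:n) if (f[i, j] > 0) s <- s + f[i, j] * log(f[i, j])
    H[j] <- -s / log(n)
  }
  W <- numeric(m)
  for (j in 1:m) W[j] <- (1 - H[j]) / sum(1 - H)
  z <- matrix(0, n, m)
  for (i in 1:n) for (j in 1:m) z[i, j] <- W[j] * b[i, j]
  zp <- numeric(m); zn <- numeric(m)
  for (j in 1:m) { zp[j] <- max(z[, j]); zn[j] <- min(z[, j]) }
  cei <- numeric(n)
  for (i in 1:n) {
    dp <- 0; dn <- 0
    for (j in 1:m) {
      dp <- dp + (zp[j] - z[i, j])^2
      dn <- dn + (zn[j] - z[i, j])^2
    }
    cei[i] <- sqrt(dn) / (sqrt(dp) + sqrt(dn))
  }
  names(cei) <- rownames(x)
  list(b = b, f = f, H = H, W = W, cei = cei)
}

# Fine-grid numeric integral of the piecewise-linear interpolant of a
# flux series (kg/ha/h over days), in kg/ha. Sampling knots are part of
# the grid so the interpolant is integrated without discretization error.
oracle_integrate <- function(days, flux, n_grid = 20001) {
  g <- sort(unique(c(days, seq(min(days), max(days), length.out = n_grid))))
  fg <- approx(days, flux, xout = g)$y
  sum((fg[-1] + fg[-length(fg)]) / 2 * diff(g)) * 24
}

# Small helper: a trimmed configuration for simulation studies that only
# need some streams (keeps recovery loops fast).
two_rotation_config <- function(accrual = c(A = 2.0, B = 0.5),
                                conc_noise_sd = rep(0.1, 6),
                                n_years = 6L, seed = 1L) {
  rot <- list(
    list(id = "A", cycle_years = 1L,
         crops = data.frame(year_in_cycle = 1L, crop = "winter_wheat")),
    list(id = "B", cycle_years = 1L,
         crops = data.frame(year_in_cycle = 1L, crop = "summer_maize"))
  )
  experiment_config(
    rotations = rot, n_replicates = 2L, n_years = n_years, seed = seed,
    soil = list(accrual = accrual, conc_noise_sd = conc_noise_sd),
    flux = list(annual_n2o_kgN = c(A = 8.9, B = 4.0),
                annual_ch4_kg = c(A = -2.0, B = -3.0),
                fert_days = list(A = list(c(5, 170, 250, 285)),
                                 B = list(c(5, 170, 250, 285))))
  )
}
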