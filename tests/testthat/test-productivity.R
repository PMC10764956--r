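# Equivalent yield, economic benefit, protein and nutrition yield.

test_that("equivalent yield is the price-ratio scaling of yield", {
  expect_equal(equivalent_yield(6000, 2.8, 2.8), 6000)
  expect_equal(equivalent_yield(5000, 7, 2.8), 12500)
  expect_equal(equivalent_yield(0, 7, 2.8), 0)
  expect_error(equivalent_yield(5000, 7, 0), "positive")
  # currency invariance: rescaling all prices cancels
  expect_equal(equivalent_yield(5000, 7 * 3, 2.8 * 3),
               equivalent_yield(5000, 7, 2.8))
  # homogeneous of degree 1 in yield
  expect_equal(equivalent_yield(2 * 5000, 7, 2.8),
               2 * equivalent_yield(5000, 7, 2.8))
})

test_that("economic benefit deflates revenue by the CPI ratio", {
  cpi <- data.frame(year = c(2008, 2016), cpi = c(100, 120))
  # break-even: nominal revenue equals cost at the base year
  expect_equal(economic_benefit(4000, 2, 8000, 2008, cpi), 0)
  expect_equal(economic_benefit(6000, 2.5, 8000, 2016, cpi), 10000)
  # base-year identity: deflator 1 gives nominal revenue minus cost
  expect_equal(economic_benefit(6000, 2.5, 8000, 2008, cpi),
               6000 * 2.5 - 8000)
  # doubling CPI_j doubles only the revenue term
  cpi2 <- data.frame(year = c(2008, 2016), cpi = c(100, 240))
  expect_equal(economic_benefit(6000, 2.5, 0, 2016, cpi2),
               2 * economic_benefit(6000, 2.5, 0, 2016, cpi))
  expect_error(economic_benefit(1, 1, 1, 2019, cpi), "2019")
  expect_error(economic_benefit(1, 1, 1, 2016,
                                data.frame(year = 2016, cpi = 100)),
               "base year")
})

test_that("protein yield is yield times protein fraction", {
  expect_equal(protein_yield(6000, 0.13), 780)
  expect_equal(protein_yield(6000, 0), 0)
  expect_equal(protein_yield(6000, 1), 6000)
  expect_error(protein_yield(6000, 1.2), "\\[0, 1\\]")
})

test_that("nutrition composite reduces, symmetrizes and matches a hand oracle", {
  nut <- data.frame(crop = c("w", "m"), protein = c(0.14, 0.09),
                    fat = c(0.02, 0.04))
  rec <- data.frame(rotation = c("R1", "R1", "R2"),
                    crop = c("w", "m", "w"),
                    yield_kg_ha = c(6000, 7000, 9000))
  # protein-only weights reproduce the protein-yield ordering
  res <- nutrition_yield(rec, nut, weights = c(protein = 1, fat = 0))
  pc <- c(R1 = 6000 * 0.14 + 7000 * 0.09, R2 = 9000 * 0.14)
  expect_equal(order(res$composite), order(pc))
  # identical rotations score identically
  rec_same <- data.frame(rotation = c("R1", "R2"), crop = "w",
                         yield_kg_ha = 5000)
  res_same <- nutrition_yield(rec_same, nut)
  expect_equal(unname(diff(res_same$composite)), 0)
  # three-rotation hand oracle with uneven weights
  nut2 <- data.frame(crop = c("x", "y", "z"), n1 = c(0.5, 0.2, 0.5),
                     n2 = c(0.1, 0.3, 0.35))
  rec2 <- data.frame(rotation = c("A", "B", "C"), crop = c("x", "y", "z"),
                     yield_kg_ha = c(100, 200, 90))
  # nutrient yields: A (50, 10), B (40, 60), C (45, 31.5)
  # min-max: n1 (1, 0, 0.5), n2 (0, 1, 0.43)
  res2 <- nutrition_yield(rec2, nut2, weights = c(n1 = 0.75, n2 = 0.25))
  expect_equal(unname(res2$composite["A"]), 0.75)
  expect_equal(unname(res2$composite["B"]), 0.25)
  expect_equal(unname(res2$composite["C"]),
               0.75 * 0.5 + 0.25 * (31.5 - 10) / 50, tolerance = 1e-12)
  expect_error(nutrition_yield(data.frame(rotation = "A", crop = "q",
                                          yield_kg_ha = 1), nut2), "q")
})

test_that("rotation metrics annualize as cycle sum over cycle years", {
  expect_equal(annualize_rotation(12000, 1), 12000)
  expect_equal(annualize_rotation(c(18000, 13000), 2), 15500)
  # a fallow season simply contributes nothing
  expect_equal(annualize_rotation(c(18000, 0, 13000), 2), 15500)
  expect_error(annualize_rotation(c(1, 2), 2, rotation = c("A", "B")),
               "more than one rotation")
  expect_error(annualize_rotation(1, 0), "cycle_years")
})
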