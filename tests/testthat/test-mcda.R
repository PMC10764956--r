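# Entropy-weighted TOPSIS comprehensive evaluation index.

test_that("min-max normalization maps extremes per direction", {
  x <- cbind(a = c(2, 4, 10), b = c(3, 1, 2))
  b <- normalize_matrix(x, c(a = "positive", b = "negative"))
  expect_equal(unname(b[, "a"]), c(0, 0.25, 1))
  # negative direction: the column minimum scores 1
  expect_equal(unname(b[, "b"]), c(0, 1, 0.5))
  expect_true(all(b >= 0 & b <= 1))
  expect_error(normalize_matrix(cbind(a = c(1, 1, 1), b = c(1, 2, 3)),
                                c(a = "positive", b = "positive")),
               "degenerate criterion.*a")
  expect_error(normalize_matrix(x[1, , drop = FALSE],
                                c(a = "positive", b = "positive")),
               "2 alternatives")
})

test_that("entropy weighting rewards informative criteria", {
  # a uniform nonzero column is maximally entropic: H = 1
  b <- cbind(u = c(0.5, 0.5, 0.5), v = c(1, 0.2, 0.6))
  ew <- entropy_weights(b)
  expect_equal(unname(ew$entropy["u"]), 1, tolerance = 1e-12)
  expect_equal(unname(ew$weights["u"]), 0, tolerance = 1e-12)
  expect_equal(unname(ew$weights["v"]), 1, tolerance = 1e-12)
  expect_equal(sum(ew$weights), 1, tolerance = 1e-12)
  # spec'd 3x2 matrix where one column takes the zero-shift path
  b2 <- cbind(c1 = c(1, 0, 0.5), c2 = c(0.5, 0.5, 0.5))
  got <- entropy_weights(b2)
  f1 <- (1 + b2[, "c1"]) / sum(1 + b2[, "c1"])  # shifted proportions
  H1 <- -sum(f1 * log(f1)) / log(3)
  expect_equal(unname(got$entropy["c1"]), H1, tolerance = 1e-12)
  expect_equal(unname(got$proportions[, "c1"]), unname(f1), tolerance = 1e-12)
  expect_equal(unname(got$weights),
               c(1 - H1, 0) / (1 - H1), tolerance = 1e-12)
  expect_error(entropy_weights(b2[1, , drop = FALSE]), "2 alternatives")
})

test_that("TOPSIS closeness is 1 at the positive ideal and 0 at the negative", {
  b <- rbind(best = c(1, 1, 1), worst = c(0, 0, 0), mid = c(0.5, 0.2, 0.8))
  w <- c(0.5, 0.3, 0.2)
  res <- topsis_cei(b, w)
  expect_equal(unname(res$cei["best"]), 1)
  expect_equal(unname(res$cei["worst"]), 0)
  expect_true(res$cei["mid"] > 0 && res$cei["mid"] < 1)
  expect_equal(unname(res$rank[c("best", "mid", "worst")]), c(1L, 2L, 3L))
  expect_error(topsis_cei(b, c(0.5, 0.5)), "one weight")
  expect_error(topsis_cei(rbind(a = c(1, 1), b = c(1, 1)), c(0.5, 0.5)),
               "degenerate")
})

test_that("full chain equals a brute-force evaluation on random matrices", {
  set.seed(2024)
  for (k in 1:20) {
    n <- sample(3:6, 1)       # alternatives
    m <- sample(2:7, 1)       # criteria
    x <- matrix(rnorm(n * m, 100, 30), n, m,
                dimnames = list(paste0("alt", 1:n), paste0("crit", 1:m)))
    dirs <- setNames(sample(c("positive", "negative"), m, replace = TRUE),
                     colnames(x))
    got <- cei(x, dirs)
    want <- oracle_cei(x, dirs[colnames(x)])
    expect_equal(unname(got$normalized), unname(want$b), tolerance = 1e-12)
    expect_equal(unname(got$weights), unname(want$W), tolerance = 1e-12)
    expect_equal(unname(got$cei), unname(want$cei), tolerance = 1e-12)
    expect_true(all(got$cei >= 0 & got$cei <= 1))
    expect_equal(sum(got$weights), 1, tolerance = 1e-12)
  }
})

test_that("CEI is scale invariant and respects dominance", {
  set.seed(77)
  x <- matrix(runif(5 * 4, 10, 20), 5, 4,
              dimnames = list(paste0("a", 1:5), paste0("c", 1:4)))
  dirs <- setNames(rep("positive", 4), colnames(x))
  base <- cei(x, dirs)
  scaled <- x
  scaled[, 2] <- x[, 2] * 1000  # rescale one raw criterion column
  expect_equal(cei(scaled, dirs)$cei, base$cei, tolerance = 1e-12)
  # a strictly dominating alternative ranks first
  x2 <- rbind(x, top = apply(x, 2, max) + 1)
  res <- cei(x2, dirs)
  expect_equal(unname(res$rank["top"]), 1L)
  expect_true(all(res$cei["top"] >= res$cei))
  # two alternatives, one criterion: closeness is exactly {1, 0}
  pair <- cei(matrix(c(3, 7), 2, 1,
                     dimnames = list(c("lo", "hi"), "c")),
              c(c = "positive"))
  expect_equal(unname(sort(pair$cei)), c(0, 1))
})
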