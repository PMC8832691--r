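# 2D global gamma: closed-form cases, oracle equivalence, monotonicity.

ti_of <- function(m) transmissionImage(m)

test_that("an identical pair gives gamma 0 everywhere evaluated", {
  set.seed(2)
  m <- matrix(runif(64 * 48, 0, 10), 64, 48)
  g <- gammaIndex(ti_of(m), ti_of(m), gammaCriteria(3, 3))
  expect_equal(passRate(g), 100)
  expect_equal(meanGamma(g), 0)
  ev <- gammaMap(g)[!is.na(gammaMap(g))]
  expect_true(all(ev == 0))
  # NaN exactly where the reference is below 5% of its maximum
  expect_identical(is.na(gammaMap(g)), m < 0.05 * max(m))
  expect_identical(nEvaluated(g), sum(m >= 0.05 * max(m)))
})

test_that("a uniform 5% overdose against a uniform reference gives gamma 5/3 everywhere", {
  # closed-form analysis: no spatial structure, so no DTA rescue; the dose
  # term is 5 / 3 at every displacement and gamma = 5/3, pass rate 0
  ref <- matrix(10, 32, 24)
  ev <- matrix(10.5, 32, 24)
  g <- gammaIndex(ti_of(ref), ti_of(ev), gammaCriteria(3, 3))
  expect_equal(max(abs(gammaMap(g) - 5 / 3)), 0, tolerance = 1e-9)
  expect_equal(passRate(g), 0)
  expect_equal(meanGamma(g), 5 / 3, tolerance = 1e-9)
})

test_that("optimized search equals the exhaustive oracle on random pairs", {
  set.seed(77)
  for (rep in 1:25) {
    a <- matrix(runif(16 * 12, 0, 1), 16, 12)
    b <- a + matrix(rnorm(16 * 12, 0, 0.05), 16, 12)
    b[b < 0] <- 0
    cr <- gammaCriteria(sample(c(2, 3), 1), sample(c(2, 3), 1))
    g1 <- gammaIndex(a, b, cr, pitch = 2.5)
    g2 <- gammaIndex(a, b, cr, pitch = 2.5, exhaustive = TRUE)
    expect_lt(max(abs(gammaMap(g1) - gammaMap(g2)), na.rm = TRUE), 0.01)
  }
})

test_that("gamma is invariant under joint rescaling (global normalization homogeneity)", {
  set.seed(3)
  a <- matrix(runif(32 * 24, 0, 5), 32, 24)
  b <- a * (1 + matrix(rnorm(32 * 24, 0, 0.03), 32, 24))
  b[b < 0] <- 0
  g1 <- gammaIndex(ti_of(a), ti_of(b), gammaCriteria(3, 3))
  g2 <- gammaIndex(ti_of(7.3 * a), ti_of(7.3 * b), gammaCriteria(3, 3))
  expect_equal(gammaMap(g1), gammaMap(g2), tolerance = 1e-9)
})

test_that("loosening criteria never increases gamma (pointwise monotonicity)", {
  set.seed(5)
  a <- matrix(runif(32 * 24, 0, 5), 32, 24)
  b <- a + matrix(rnorm(32 * 24, 0, 0.1), 32, 24)
  b[b < 0] <- 0
  # hold the interpolation grid fixed so the candidate sets are nested
  loose <- gammaIndex(ti_of(a), ti_of(b), gammaCriteria(3, 3), stepMm = 0.25)
  tight <- gammaIndex(ti_of(a), ti_of(b), gammaCriteria(2, 2), stepMm = 0.25)
  expect_true(all(gammaMap(loose) <= gammaMap(tight) + 1e-9, na.rm = TRUE))
  expect_gte(passRate(loose), passRate(tight))
  expect_lte(meanGamma(loose), meanGamma(tight))
})

test_that("gamma is only approximately symmetric in its arguments", {
  # constructed asymmetry: a hot spike in one image is rescued by DTA from
  # a neighbouring match when evaluated, but not when it is the reference
  ref <- matrix(1, 16, 12); ref[8, 6] <- 2
  ev <- matrix(1, 16, 12)
  cr <- gammaCriteria(3, 3, thresholdPercent = 0)
  g_ab <- gammaIndex(ti_of(ref), ti_of(ev), cr)
  g_ba <- gammaIndex(ti_of(ev), ti_of(ref), cr)
  expect_false(isTRUE(all.equal(gammaMap(g_ab)[8, 6], gammaMap(g_ba)[8, 6])))
})

test_that("degenerate inputs are rejected", {
  a <- matrix(1, 16, 12)
  expect_error(gammaIndex(a, matrix(1, 12, 16), gammaCriteria(3, 3)),
               "do not match")
  expect_error(gammaIndex(matrix(0, 16, 12), a, gammaCriteria(3, 3)),
               "nothing to evaluate")
})

test_that("verifyField reports both criteria with the measured image as reference", {
  set.seed(11)
  m <- matrix(runif(64 * 48, 1, 10), 64, 48)
  res <- verifyField(ti_of(m), ti_of(m))
  expect_named(res, c("3%/3mm", "2%/2mm"))
  expect_equal(passRate(res[["3%/3mm"]]), 100)
  expect_equal(passRate(res[["2%/2mm"]]), 100)
  # same pair: looser criteria pass at least as well
  b <- m * (1 + matrix(rnorm(64 * 48, 0, 0.02), 64, 48))
  b[b < 0] <- 0
  res2 <- verifyField(ti_of(b), ti_of(m))
  expect_gte(passRate(res2[["3%/3mm"]]), passRate(res2[["2%/2mm"]]))
  expect_lte(meanGamma(res2[["3%/3mm"]]), meanGamma(res2[["2%/2mm"]]))
})
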