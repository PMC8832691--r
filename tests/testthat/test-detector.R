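# Synthetic detector engine: fluence geometry, attenuation physics, the
# dose-to-image transform, error injection, dataset assembly.

model <- detectorModel()
grid <- quick_grid()

test_that("a square aperture magnifies by sid/sad = 1.5 at the EPID plane", {
  flu <- fluenceAtEpid(square_beam(75), model, grid)
  prof <- flu[, which.min(abs(grid$y))]
  half <- max(flu) / 2
  xr <- grid$x[grid$x > 0]
  pr <- prof[grid$x > 0]
  edge <- stats::approx(pr, xr, xout = half, ties = mean)$y
  expect_equal(edge, 112.5, tolerance = 0.02)  # 75 mm x 1.5
})

test_that("fluence is linear in MU and in segment weights", {
  b1 <- square_beam(60, mu = 100)
  b2 <- square_beam(60, mu = 200)
  f1 <- fluenceAtEpid(b1, model, grid)
  f2 <- fluenceAtEpid(b2, model, grid)
  expect_equal(f2, 2 * f1, tolerance = 1e-12)
  # two equal identical segments == one segment at the same total weight
  cps3 <- list(controlPoint(0, 0, rep(60, 60), rep(-60, 60), c(-60, 60), c(-60, 60)),
               controlPoint(1, 0.5, rep(60, 60), rep(-60, 60), c(-60, 60), c(-60, 60)),
               controlPoint(2, 1, rep(60, 60), rep(-60, 60), c(-60, 60), c(-60, 60)))
  b3 <- beamField("b3", 100, cps3)
  expect_equal(fluenceAtEpid(b3, model, grid), f1, tolerance = 1e-12)
})

test_that("sliding-gap fluence equals the per-interval accumulation oracle", {
  # 20 mm gap sliding across three control points; oracle accumulates the
  # trapezoid-weighted aperture indicator per pixel on a 0.5 mm grid,
  # computed independently from leaf geometry
  pos <- list(c(-60, -40), c(-10, 10), c(40, 60))
  w <- c(0, 0.35, 1)
  cps <- lapply(1:3, function(k)
    controlPoint(k - 1L, w[k], rep(pos[[k]][2], 60), rep(pos[[k]][1], 60),
                 c(-80, 80), c(-80, 80)))
  beam <- beamField("slide", 1, cps)
  m0 <- detectorModel(penumbraSigmaMm = 0, hornCoeff = 0)
  fine <- epidGrid(480L, 360L, 0.5)
  flu <- fluenceAtEpid(beam, m0, fine)
  inside <- function(x, lohi) as.numeric(x > lohi[1] & x < lohi[2])
  xi <- fine$x / 1.5
  yi <- fine$y / 1.5
  open_y <- as.numeric(abs(yi) < 80 & abs(yi) <= 200)
  oracle <- matrix(0, length(xi), length(yi))
  for (k in 1:2) {
    mk <- outer(inside(xi, pos[[k]]), open_y)
    mk1 <- outer(inside(xi, pos[[k + 1]]), open_y)
    oracle <- oracle + (w[k + 1] - w[k]) * (mk + mk1) / 2
  }
  sid <- 1500
  invsq <- 1000^2 / (sid^2 + outer(fine$x, fine$y, function(x, y) x^2 + y^2))
  expect_lt(max(abs(flu - oracle * invsq)), 1e-9)
})

test_that("slab attenuation follows exp(-mu t) on the central axis", {
  b <- square_beam(75)
  d0 <- waterDose(b, slabPhantom(0), model, grid = grid, noise = FALSE)
  d10 <- waterDose(b, slabPhantom(10), model, grid = grid, noise = FALSE)
  ic <- which.min(abs(grid$x)); jc <- which.min(abs(grid$y))
  # closed-form exponential oracle
  expect_equal(imageValues(d10)[ic, jc] / imageValues(d0)[ic, jc],
               exp(-0.0457 * 10), tolerance = 1e-4)
  # adding t cm multiplies by exp(-mu t)
  d15 <- waterDose(b, slabPhantom(15), model, grid = grid, noise = FALSE)
  expect_equal(imageValues(d15)[ic, jc] / imageValues(d10)[ic, jc],
               exp(-0.0457 * 5), tolerance = 1e-4)
})

test_that("noise is seeded, reproducible, and at the nominal level", {
  b <- square_beam(75)
  d1 <- waterDose(b, slabPhantom(10), model, grid = grid, seed = 5)
  d2 <- waterDose(b, slabPhantom(10), model, grid = grid, seed = 5)
  expect_identical(imageValues(d1), imageValues(d2))
  clean <- waterDose(b, slabPhantom(10), model, grid = grid, noise = FALSE)
  d3 <- waterDose(b, slabPhantom(10), model, grid = grid, seed = 6)
  res <- imageValues(d3) - imageValues(clean)
  infield <- imageValues(clean) > 0.8 * max(imageValues(clean))
  # noise-statistics oracle: sd = noiseRel * sqrt(D * Dmax) ~ 1% of Dmax
  expect_lt(abs(sd(res[infield]) / max(imageValues(clean)) - 0.01), 0.001)
})

test_that("noiseless dose scales exactly with MU", {
  p <- slabPhantom(12)
  d1 <- waterDose(square_beam(50, mu = 80), p, model, grid = grid, noise = FALSE)
  d2 <- waterDose(square_beam(50, mu = 160), p, model, grid = grid, noise = FALSE)
  expect_equal(imageValues(d2), 2 * imageValues(d1), tolerance = 1e-12)
})

test_that("anterior shifts leave the homogeneous-slab dose invariant", {
  b <- square_beam(75)
  base <- waterDose(b, slabPhantom(10), model, grid = grid, noise = FALSE)
  for (mm in c(5, 10, 20)) {
    pert <- injectError(b, slabPhantom(10),
                        errorSpec("iso_shift_anterior", mm))
    shifted <- waterDose(pert$beam, pert$phantom, model, grid = grid,
                         noise = FALSE)
    expect_lt(max(abs(imageValues(shifted) - imageValues(base))) /
                max(imageValues(base)), 0.001)
  }
})

test_that("lateral shifts move an insert's shadow by shift x magnification", {
  b <- square_beam(75)
  ph <- slabPhantom(10, inserts = list(list(
    type = "box", x = c(-10, 10), depth = c(-30, 30), z = c(-150, 150),
    density = 0.2)))
  d0 <- waterDose(b, ph, model, grid = grid, noise = FALSE)
  pert <- injectError(b, ph, errorSpec("iso_shift_lateral", 10))
  d1 <- waterDose(pert$beam, pert$phantom, model, grid = grid, noise = FALSE)
  jc <- which.min(abs(grid$y))
  shadow <- function(d) grid$x[which.max(imageValues(d)[, jc])]
  # the insert is less dense, so its shadow is the profile maximum;
  # a 10 mm phantom shift projects to 15 mm at the EPID plane
  expect_equal(abs(shadow(d1) - shadow(d0)), 15, tolerance = grid$pitch)
})

test_that("the detector transform reduces to identity when degenerate", {
  b <- square_beam(60)
  clean <- waterDose(b, slabPhantom(5), model, grid = grid, noise = FALSE)
  ident <- detectorModel(gain = 1, oarCoeffs = 0, hornCoeff = model@hornCoeff,
                         glareWeights = numeric(0), glareSigmaMm = numeric(0),
                         glareCoreSigmaMm = 1e-6)
  ti <- trueResponse(clean, ident, 128L, 96L)
  direct <- cropResample(clean, 128L, 96L)
  expect_equal(imageValues(ti), imageValues(direct), tolerance = 1e-6)
})

test_that("the glare kernel is normalized: uniform-disc centre is preserved", {
  disc <- matrix(0, length(grid$x), length(grid$y))
  disc[outer(grid$x^2, grid$y^2, "+") < 100^2] <- 1
  pd <- planarDose(disc, c(grid$pitch, grid$pitch))
  m1 <- detectorModel(gain = 1, oarCoeffs = 0)
  ti <- trueResponse(pd, m1, 128L, 96L)
  centre <- imageValues(ti)[64:65, 48:49]
  expect_lt(max(abs(centre - 1)), 1e-4)
})

test_that("normalized dose and image profiles of a 15 x 15 cm field disagree by about 10% in-field", {
  clean <- waterDose(square_beam(75), slabPhantom(20), model, grid = grid,
                     noise = FALSE)
  ti <- trueResponse(clean, model, 128L, 96L)
  nd <- imageValues(normalizeMax(cropResample(clean, 128L, 96L)))
  nt <- imageValues(normalizeMax(ti))
  tx <- (seq_len(128) - 64.5) * 400 / 128
  jn <- which.min(abs((seq_len(96) - 48.5)))
  sel <- abs(tx) <= 105  # in-field, clear of the penumbra
  disc <- abs(nd[sel, jn] - nt[sel, jn])
  expect_gt(max(disc), 0.07)
  expect_lt(max(disc), 0.13)
  # and the discrepancy grows off-axis
  expect_lt(abs(nd[65, jn] - nt[65, jn]), 0.01)
})

test_that("error injection follows the protocol arithmetic", {
  b <- square_beam(60, mu = 100)
  ph <- slabPhantom(10)
  expect_equal(monitorUnits(injectError(b, ph, errorSpec("mu_scale", 5))$beam), 105)
  expect_equal(monitorUnits(injectError(b, ph, errorSpec("mu_scale", -5))$beam), 95)
  # Ed1: every gap widens by the stated amount, 2.5 mm per bank
  e1 <- injectError(b, ph, errorSpec("mlc_open_all", 5))$beam
  cp0 <- controlPoints(b)[[1]]; cp1 <- controlPoints(e1)[[1]]
  expect_equal(cp1@mlcA - cp1@mlcB, (cp0@mlcA - cp0@mlcB) + 5)
  expect_equal(cp1@mlcA, cp0@mlcA + 2.5)
  # Ed2: both banks shift together, gap unchanged
  e2 <- injectError(b, ph, errorSpec("mlc_bank_shift", 2))$beam
  cp2 <- controlPoints(e2)[[1]]
  expect_equal(cp2@mlcA, cp0@mlcA + 2)
  expect_equal(cp2@mlcB, cp0@mlcB + 2)
  # Ed3: only in-field bank-B leaves move
  mixed <- controlPoint(0, 0, c(rep(0, 30), rep(40, 30)),
                        c(rep(0, 30), rep(-40, 30)))
  bm <- beamField("m", 50, list(mixed, controlPoint(1, 1, c(rep(0, 30), rep(40, 30)),
                                                    c(rep(0, 30), rep(-40, 30)))))
  e3 <- injectError(bm, ph, errorSpec("mlc_bankB_infield_shift", 5))$beam
  cp3 <- controlPoints(e3)[[1]]
  expect_equal(cp3@mlcB[1:30], rep(0, 30))      # closed pairs untouched
  expect_equal(cp3@mlcB[31:60], rep(-45, 30))   # in-field leaves widen
  # Ed4: central four pairs only
  e4 <- injectError(b, ph, errorSpec("mlc_central4_open", 10))$beam
  cp4 <- controlPoints(e4)[[1]]
  expect_equal(cp4@mlcA[29:32], cp0@mlcA[29:32] + 5)
  expect_equal(cp4@mlcA[c(1:28, 33:60)], cp0@mlcA[c(1:28, 33:60)])
  # Ee: slab stacked on top
  e5 <- injectError(b, ph, errorSpec("slab_add", 10))$phantom
  expect_equal(e5@addedTopCm, 1)
  expect_error(errorSpec("not_a_kind", 1), "unknown error kind")
})

test_that("mu_scale multiplies the noiseless image exactly", {
  b <- square_beam(60)
  ph <- slabPhantom(10)
  base <- trueResponse(waterDose(b, ph, model, grid = grid, noise = FALSE),
                       model, 128L, 96L)
  pert <- injectError(b, ph, errorSpec("mu_scale", 7))
  up <- trueResponse(waterDose(pert$beam, pert$phantom, model, grid = grid,
                               noise = FALSE), model, 128L, 96L)
  expect_equal(imageValues(up), 1.07 * imageValues(base), tolerance = 1e-9)
})

test_that("dataset generation is reproducible with disjoint splits of the requested sizes", {
  b1 <- generateDataset(c(6L, 2L, 2L), nx = 64L, ny = 48L, seed = 31L)
  b2 <- generateDataset(c(6L, 2L, 2L), nx = 64L, ny = 48L, seed = 31L)
  expect_identical(b1@inputs, b2@inputs)
  expect_identical(b1@targets, b2@targets)
  sp <- datasetSplit(b1)
  expect_identical(lengths(sp), c(train = 6L, val = 2L, test = 2L))
  expect_length(intersect(sp$train, c(sp$val, sp$test)), 0L)
  expect_length(intersect(sp$val, sp$test), 0L)
  b3 <- generateDataset(c(1L, 1L, 1L), nx = 64L, ny = 48L, seed = 1L)
  expect_identical(lengths(datasetSplit(b3)), c(train = 1L, val = 1L, test = 1L))
  expect_false(identical(
    b1@inputs[[1]],
    generateDataset(c(1L, 0L, 0L), nx = 64L, ny = 48L, seed = 32L)@inputs[[1]]))
})
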