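# Equivalent-EPID plane extraction, crop/resampling, measured-image import.

test_that("extractPlane returns the exact stored plane on a grid hit", {
  set.seed(8)
  vox <- array(runif(24 * 11 * 20), c(24, 11, 20))
  vol <- doseVolume(vox, spacing = c(10, 100, 10),
                    origin = c(-115, -500, -95))
  # y planes at -500, -400, ..., 500; depth 500 is plane 11
  pl <- extractPlane(vol, 50)
  expect_identical(imageValues(pl), vox[, 11, ])
  expect_identical(gridSpacing(pl), c(10, 10))
})

test_that("extractPlane interpolates a depth-linear dose field exactly", {
  # analytic-field oracle: D = depth(mm) -> plane at 500 mm is uniformly 500
  ny <- 14L
  y <- seq(420, 550, by = 10)
  vox <- array(rep(y, each = 6), c(6, length(y), 5))
  vol <- doseVolume(vox, spacing = c(20, 10, 20),
                    origin = c(-50, 420, -40))
  pl <- extractPlane(vol, 50, method = "linear")
  expect_equal(imageValues(pl), matrix(500, 6, 5))
  y2 <- seq(424, 554, by = 10)
  vox2 <- array(rep(y2, each = 6), c(6, length(y2), 5))
  pl2 <- extractPlane(doseVolume(vox2, spacing = c(20, 10, 20),
                                 origin = c(-50, 424, -40)), 50)
  expect_equal(imageValues(pl2), matrix(500, 6, 5), tolerance = 1e-12)
  expect_error(extractPlane(vol, 80), "outside")
})

test_that("a 512 x 176 Monte-Carlo-export plane is accepted and a constant field passes through", {
  pl <- planarDose(matrix(7.5, 512, 176), spacing = c(500 / 512, 352 / 176))
  ti <- cropResample(pl)
  expect_identical(dim(imageValues(ti)), c(256L, 192L))
  expect_equal(pixelPitch(ti), c(1.5625, 1.5625))
  expect_true(all(abs(imageValues(ti) - 7.5) < 1e-12))
})

test_that("cropResample reproduces a separable linear ramp at target pixel centres", {
  # closed-form bilinear oracle: bilinear sampling of D(x, y) = x is exact
  nx <- 512L; ny <- 176L
  sx <- (seq_len(nx) - (nx + 1) / 2) * 500 / 512
  sy <- (seq_len(ny) - (ny + 1) / 2) * 2
  pl <- planarDose(outer(sx, rep(1, ny)) + 1000, spacing = c(500 / 512, 2))
  ti <- cropResample(pl, 256L, 192L)
  tx <- (seq_len(256) - 128.5) * 1.5625
  expected <- outer(tx, rep(1, 192)) + 1000
  expect_lt(max(abs(imageValues(ti) - expected) / expected), 1e-9)
})

test_that("cropResample errors when the window is not covered", {
  pl <- planarDose(matrix(1, 64, 64), spacing = c(2, 2))  # 128 mm extent
  expect_error(cropResample(pl), "cover")
})

test_that("measured-image import block-averages 4 x 4 exactly", {
  expect_equal(imageValues(loadMeasuredTI(matrix(100, 1024, 768))),
               matrix(100, 256, 192))
  # block-mean oracle: a pixel checkerboard averages to exactly 0.5 in
  # every 4 x 4 block
  img <- outer(seq_len(1024) - 1, seq_len(768) - 1, function(i, j) (i + j) %% 2)
  expect_equal(imageValues(loadMeasuredTI(img)), matrix(0.5, 256, 192))
  expect_equal(provenance(loadMeasuredTI(img)), "measured")
  expect_error(loadMeasuredTI(matrix(0, 512, 384)), "1024 x 768")
  # panel geometry: 1024 px over 400 mm -> 0.390625 mm source pitch,
  # preserved as 4 x 1.5625 mm analysis pitch
  expect_equal(400 / 1024 * 4, 1.5625)
})

test_that("resampling paths commute with global scaling and share pixel geometry", {
  set.seed(12)
  src <- matrix(runif(512 * 176, 1, 2), 512, 176)
  pl <- planarDose(src, spacing = c(500 / 512, 2))
  a <- imageValues(cropResample(pl))
  pl_scaled <- planarDose(3.7 * src, spacing = c(500 / 512, 2))
  expect_equal(imageValues(cropResample(pl_scaled)), 3.7 * a, tolerance = 1e-12)
  img <- matrix(runif(1024 * 768), 1024, 768)
  expect_equal(imageValues(loadMeasuredTI(2.5 * img)),
               2.5 * imageValues(loadMeasuredTI(img)), tolerance = 1e-12)
  # both paths produce the same analysis grid geometry
  expect_identical(pixelPitch(cropResample(pl)), pixelPitch(loadMeasuredTI(img)))
})

test_that("normalizeMax rescales to unit maximum for all carriers", {
  m <- matrix(c(1, 2, 4, 8), 2)
  expect_equal(max(normalizeMax(m)), 1)
  ti <- transmissionImage(matrix(runif(64 * 48, 0.1, 9), 64, 48))
  expect_equal(max(imageValues(normalizeMax(ti))), 1)
})
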