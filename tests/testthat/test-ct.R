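# Combined-CT construction: couch substitution, rotation, extension, slab.

make_ct <- function(n = 40L, spacing = 5) {
  # smooth HU field (no sharp edges), centred on the isocentre
  ax <- (seq_len(n) - (n + 1) / 2) * spacing
  vox <- array(0, c(n, n, 8L))
  sl <- outer(ax, ax, function(x, y)
    -200 + 150 * cos(x / 60) * cos(y / 70) + 0.4 * x)
  for (k in 1:8) vox[, , k] <- sl
  ctVolume(vox, c(spacing, spacing, 5))
}

test_that("replaceCouch changes exactly the masked voxels", {
  ct <- make_ct()
  empty <- array(FALSE, dim(voxels(ct)))
  expect_identical(voxels(replaceCouch(ct, empty, -300)), voxels(ct))
  full <- array(TRUE, dim(voxels(ct)))
  expect_true(all(voxels(replaceCouch(ct, full, -300)) == -300))
  set.seed(4)
  mask <- array(runif(length(voxels(ct))) < 0.2, dim(voxels(ct)))
  out <- replaceCouch(ct, mask, -123)
  # voxel-count oracle
  expect_identical(sum(voxels(out) == -123 & voxels(ct) != -123),
                   sum(mask & voxels(ct) != -123))
  expect_identical(voxels(out)[!mask], voxels(ct)[!mask])
  bad <- array(FALSE, dim(voxels(ct)) + c(1L, 0L, 0L))
  expect_error(replaceCouch(ct, bad, -300), "shape")
})

test_that("rotation by 0 is the identity and two 180s recompose the volume", {
  ct <- make_ct()
  expect_identical(voxels(rotateAxial(ct, 0)), voxels(ct))
  twice <- rotateAxial(rotateAxial(ct, 180), 180)
  # compose-and-compare oracle on a smooth phantom
  expect_lt(max(abs(voxels(twice) - voxels(ct))), 2)
})

test_that("a bright voxel 30 mm image-right of the isocentre moves anterior under 90 deg anti-clockwise", {
  n <- 41L; sp <- 2
  vox <- array(0, c(n, n, 1L))
  ct <- ctVolume(vox, c(sp, sp, sp))
  ix <- which.min(abs(ct@origin[1] + (seq_len(n) - 1) * sp - 30))
  ic <- (n + 1) / 2
  vox[ix, ic, 1] <- 1000
  ct@voxels <- vox
  rot <- rotateAxial(ct, 90)
  v <- voxels(rot)[, , 1]
  v[v < 0] <- 0
  # point-rotation oracle: mass centroid at (0, -30) (anterior), within 1 voxel
  xs <- ct@origin[1] + (seq_len(n) - 1) * sp
  cx <- sum(outer(xs, rep(1, n)) * v) / sum(v)
  cy <- sum(outer(rep(1, n), xs) * v) / sum(v)
  expect_lt(abs(cx - 0), sp)
  expect_lt(abs(cy - (-30)), sp)
})

test_that("rotation composition approximately matches the summed angle", {
  ct <- make_ct()
  ab <- rotateAxial(rotateAxial(ct, 40), 25)
  once <- rotateAxial(ct, 65)
  # compare inside the disc where both rotations keep full support
  ax <- (seq_len(40) - 20.5) * 5
  core <- outer(ax, ax, function(x, y) sqrt(x^2 + y^2)) < 60
  d <- abs(voxels(ab) - voxels(once))
  expect_lt(max(d[rep(core, 8)]), 2)
})

test_that("extendAxial pads with air to the requested extent and keeps origin bookkeeping", {
  ct <- make_ct()  # 40 voxels x 5 mm = 200 mm extent, 100 mm below iso
  ext <- extendAxial(ct, minDepthBelowIsoCm = 55)
  crd_y <- ext@origin[2] + (seq_len(dim(voxels(ext))[2]) - 1) * 5
  expect_gte(max(crd_y) - isocentre(ext)[2], 550)
  # extent-arithmetic oracle: pad voxel count
  expect_identical(dim(voxels(ext))[2] - dim(voxels(ct))[2],
                   as.integer(ceiling((550 - 97.5) / 5)))
  # pad voxels all air
  expect_true(all(voxels(ext)[, (dim(voxels(ct))[2] + 1):dim(voxels(ext))[2], ] == -1000))
  # same physical point keeps its HU
  expect_equal(huAt(ext, c(1, 1, 1)), huAt(ct, c(1, 1, 1)))
  expect_equal(huAt(ext, c(31, -21, 11)), huAt(ct, c(31, -21, 11)))
  # already-covering volume is unchanged
  expect_identical(voxels(extendAxial(ext, 52)), voxels(ext))
  expect_error(extendAxial(ct, 40), ">= 52")
})

test_that("the solid-water slab and air gap are exact", {
  ct <- extendAxial(make_ct(), 60)
  cc <- insertSolidWater(ct, airFromMm = 150)
  # scoring plane 50 cm below the isocentre is inside the slab (HU 0)
  expect_equal(huAt(cc, c(0, 500, 0)), 0)
  expect_equal(huAt(cc, c(100, 510, 0)), 0)
  # above the slab (46 cm) is air
  expect_equal(huAt(cc, c(0, 460, 0)), -1000)
  # geometry-count oracle for slab voxels
  crd_y <- cc@origin[2] + (seq_len(dim(voxels(cc))[2]) - 1) * 5
  d <- crd_y - isocentre(cc)[2]
  ny <- sum(d >= 470 & d < 520)
  crd_x <- cc@origin[1] + (seq_len(dim(voxels(cc))[1]) - 1) * 5
  nx <- sum(abs(crd_x) <= 250)
  crd_z <- cc@origin[3] + (seq_len(dim(voxels(cc))[3]) - 1) * 5
  nz <- sum(abs(crd_z) <= 200)
  expect_identical(sum(voxels(cc) == 0), nx * ny * nz)
  # slab region exactly 0, gap exactly -1000 (no interpolation bleed)
  slab <- voxels(cc)[abs(crd_x) <= 250, d >= 470 & d < 520, abs(crd_z) <= 200]
  expect_true(all(slab == 0))
  gap <- voxels(cc)[, d >= 160 & d < 470, ]
  expect_true(all(gap == -1000))
  expect_error(insertSolidWater(make_ct()), "extendAxial")
})

test_that("buildCombinedCT records rotation and only rotation touches anatomy", {
  ct <- make_ct()
  beam0 <- beams(splitPlan(randomPlan(1, gantryAngles = 0, seed = 2))[[1]])[[1]]
  cc0 <- suppressWarnings(buildCombinedCT(ct, beam0))
  expect_equal(cc0@rotationAppliedDeg, 0)
  # zero rotation: anatomy voxels are untouched (sampled at physical points
  # chosen off the voxel-boundary ties)
  for (p in list(c(1, 1, 1), c(26, -31, 11), c(-44, 41, -16)))
    expect_equal(huAt(cc0, p), huAt(ct, p))
  beam30 <- beams(splitPlan(randomPlan(1, gantryAngles = 30, seed = 2))[[1]])[[1]]
  cc30 <- suppressWarnings(buildCombinedCT(ct, beam30))
  expect_equal(cc30@rotationAppliedDeg, 30)
})

test_that("opposed lateral beams give mirror-related combined CTs", {
  ct <- syntheticPhantomCT(32L, 6)  # left-right asymmetric by construction
  b90 <- beams(splitPlan(randomPlan(1, gantryAngles = 90, seed = 2))[[1]])[[1]]
  b270 <- beams(splitPlan(randomPlan(1, gantryAngles = 270, seed = 2))[[1]])[[1]]
  cc90 <- suppressWarnings(buildCombinedCT(ct, b90))
  cc270 <- suppressWarnings(buildCombinedCT(ct, b270))
  v90 <- voxels(cc90); v270 <- voxels(cc270)
  # symmetry oracle: x-mirror of one equals the other (within interpolation)
  mirrored <- v270[rev(seq_len(dim(v270)[1])), , ]
  expect_lt(mean(abs(v90 - mirrored)), 3)
})

test_that("a CT volume round-trips through the DICOM series writer", {
  ct <- make_ct(20L, 8)
  dir <- withr::local_tempdir()
  writeCTSeries(ct, dir)
  ct2 <- readCTSeries(dir)
  expect_equal(dim(voxels(ct2)), dim(voxels(ct)))
  expect_equal(voxels(ct2), round(voxels(ct)), tolerance = 1e-9)
  expect_equal(gridSpacing(ct2), gridSpacing(ct))
  expect_equal(gridOrigin(ct2), gridOrigin(ct), tolerance = 1e-6)
})
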