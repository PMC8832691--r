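# RT plan model, DICOM round trip, plan splitting, aperture rasterisation.

test_that("a synthetic plan round-trips through the DICOM writer and reader", {
  plan <- randomPlan(3, gantryAngles = c(30, 120, 270), seed = 42)
  f <- withr::local_tempfile(fileext = ".dcm")
  writeRTPlan(plan, f)
  plan2 <- readRTPlan(f)
  expect_length(beams(plan2), 3L)
  expect_equal(vapply(beams(plan2), gantryAngle, numeric(1)), c(30, 120, 270))
  for (i in 1:3) {
    b1 <- beams(plan)[[i]]; b2 <- beams(plan2)[[i]]
    expect_equal(monitorUnits(b2), monitorUnits(b1), tolerance = 1e-7)
    expect_length(controlPoints(b2), length(controlPoints(b1)))
    for (k in seq_along(controlPoints(b1))) {
      cp1 <- controlPoints(b1)[[k]]; cp2 <- controlPoints(b2)[[k]]
      expect_equal(cp2@mlcA, cp1@mlcA, tolerance = 1e-7)
      expect_equal(cp2@mlcB, cp1@mlcB, tolerance = 1e-7)
      expect_equal(cp2@jawX, cp1@jawX, tolerance = 1e-7)
      expect_equal(cp2@weight, cp1@weight, tolerance = 1e-7)
    }
  }
})

test_that("the DICOM writer is readable by an independent implementation", {
  skip_if(Sys.which("python") == "", "python not on PATH")
  plan <- randomPlan(2, gantryAngles = c(30, 120), seed = 7)
  f <- withr::local_tempfile(fileext = ".dcm")
  writeRTPlan(plan, f)
  out <- suppressWarnings(system2("python", c("-c", shQuote(paste0(
    "import pydicom; d = pydicom.dcmread('", f, "'); ",
    "b = d.BeamSequence; ",
    "print(len(b), b[0].ControlPointSequence[0].GantryAngle, ",
    "float(d.FractionGroupSequence[0].ReferencedBeamSequence[0].BeamMeterset))"))),
    stdout = TRUE, stderr = TRUE))
  skip_if(is.null(attr(out, "status")) == FALSE && attr(out, "status") != 0,
          "pydicom unavailable")
  vals <- strsplit(tail(out, 1), " ")[[1]]
  expect_equal(as.integer(vals[1]), 2L)
  expect_equal(as.numeric(vals[2]), 30)
  expect_equal(as.numeric(vals[3]), monitorUnits(beams(plan)[[1]]),
               tolerance = 1e-6)
})

test_that("splitPlan yields single-beam zero-gantry plans conserving MU and control points", {
  plan <- randomPlan(5, gantryAngles = c(30, 120, 270, 0, 200), seed = 3)
  parts <- splitPlan(plan)
  expect_length(parts, 5L)
  # direct-summation oracle for MU and control-point conservation
  expect_equal(sum(vapply(parts, monitorUnits, numeric(1))), monitorUnits(plan))
  ncp_in <- sum(vapply(beams(plan), function(b) length(controlPoints(b)), integer(1)))
  ncp_out <- sum(vapply(parts, function(p)
    length(controlPoints(beams(p)[[1]])), integer(1)))
  expect_identical(ncp_out, ncp_in)
  for (i in seq_along(parts)) {
    b <- beams(parts[[i]])[[1]]
    expect_equal(gantryAngle(b), 0)
    expect_equal(originalGantryAngle(b), gantryAngle(beams(plan)[[i]]))
    expect_equal(monitorUnits(b), monitorUnits(beams(plan)[[i]]))
  }
})

test_that("splitPlan is idempotent on its own outputs", {
  plan <- randomPlan(2, gantryAngles = c(45, 300), seed = 9)
  once <- splitPlan(plan)[[1]]
  twice <- splitPlan(once)[[1]]
  expect_equal(beams(twice)[[1]]@controlPoints, beams(once)[[1]]@controlPoints)
  expect_equal(originalGantryAngle(beams(twice)[[1]]),
               originalGantryAngle(beams(once)[[1]]))
  expect_equal(monitorUnits(twice), monitorUnits(once))
})

test_that("splitting an empty plan errors", {
  plan <- randomPlan(1, seed = 1)
  plan@beams <- list()
  expect_error(splitPlan(plan), "empty")
})

test_that("aperture mask matches field-size and closed-field expectations", {
  g <- isoGrid(200, 200, 1)
  open <- controlPoint(0, 0, rep(75, 60), rep(-75, 60), c(-75, 75), c(-75, 75))
  m <- apertureMask(open, g)
  expect_equal(sum(m) * g$pitch^2 / 100, 225)  # 15 cm x 15 cm = 225 cm^2
  closed <- controlPoint(0, 0, rep(0, 60), rep(0, 60))
  expect_true(all(apertureMask(closed, g) == 0L))
})

test_that("aperture area equals the per-pair rectangle-sum oracle", {
  set.seed(21)
  g <- isoGrid(220, 220, 1)
  bounds <- mlcLeafBoundaries()
  for (rep in 1:5) {
    a <- runif(60, -20, 90); b <- pmin(runif(60, -90, 20), a)
    jx <- c(-80, 85); jy <- c(-95, 90)
    cp <- controlPoint(0, 0, a, b, jx, jy)
    m <- apertureMask(cp, g)
    # oracle: per leaf pair, open cells = (open x-range) x (pair y-range),
    # counted on the same cell centres but by interval arithmetic
    count_in <- function(lo, hi, centres) sum(centres > lo & centres < hi)
    expected <- 0L
    for (p in 1:60) {
      ny <- count_in(max(bounds[p], jy[1]), min(bounds[p + 1], jy[2]), g$y)
      nx <- count_in(max(b[p], jx[1]), min(a[p], jx[2]), g$x)
      expected <- expected + nx * ny
    }
    expect_identical(sum(m), expected)
  }
})

test_that("aperture mask is monotone under leaf-gap widening", {
  set.seed(5)
  g <- isoGrid(120, 120, 2)
  a <- runif(60, 0, 60); b <- pmin(runif(60, -60, 0), a)
  cp <- controlPoint(0, 0, a, b)
  cp_wide <- controlPoint(0, 0, a + 7, b - 4)
  m1 <- apertureMask(cp, g); m2 <- apertureMask(cp_wide, g)
  expect_true(all(m2[m1 == 1L] == 1L))
})

test_that("invalid plans are rejected with informative errors", {
  # bank B passing bank A
  expect_error(controlPoint(0, 0, rep(-5, 60), rep(5, 60)), "bank-B")
  # non-monotone meterset
  cps <- list(controlPoint(0, 0, rep(10, 60), rep(-10, 60)),
              controlPoint(1, 0.8, rep(10, 60), rep(-10, 60)),
              controlPoint(2, 1, rep(10, 60), rep(-10, 60)))
  expect_s4_class(beamField("b", 10, cps), "BeamField")
  cps_bad <- list(cps[[2]], cps[[1]], cps[[3]])
  expect_error(beamField("b", 10, cps_bad), "non-decreasing|start at 0")
  # mixed gantry within a beam (IMRT only)
  cps_rot <- list(controlPoint(0, 0, rep(10, 60), rep(-10, 60), gantry = 10),
                  controlPoint(1, 1, rep(10, 60), rep(-10, 60), gantry = 50))
  expect_error(beamField("b", 10, cps_rot), "static")
})
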