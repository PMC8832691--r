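# Synthetic detector-response engine: fluence at the EPID plane from MLC
# control points, water-dose simulation with MC-like noise (a stand-in for
# a Monte-Carlo dose engine), the parametric ground-truth dose-to-greyscale
# transform, delivery/setup error injection, and dataset assembly.

#' Construct the parametric detector model
#'
#' Defaults describe a 6 MV beam on a 150 cm source-imager-distance panel:
#' effective attenuation 0.0457 /cm, modest fluence horns, an off-axis
#' detector response that declines quadratically (the flood-field
#' calibration flattens the detector, removing the horns from the image but
#' not from the water dose), a two-Gaussian glare kernel, and ~1% relative
#' MC noise at the dose maximum. The horn/off-axis defaults are calibrated
#' so that the max-normalized dose and image profiles of a 15 cm x 15 cm
#' field disagree by about 10% at the in-field edge (see vignette).
#'
#' @param sadCm,sidCm,muEffPerCm,hornCoeff,oarCoeffs,glareWeights,glareSigmaMm,glareCoreSigmaMm,penumbraSigmaMm,doseSpreadSigmaMm,gain,noiseRel
#'   see [DetectorModel-class].
#' @return A [DetectorModel-class].
#' @export
detectorModel <- function(sadCm = 100, sidCm = 150, muEffPerCm = 0.0457,
                          hornCoeff = 0.06, oarCoeffs = -0.063,
                          glareWeights = 0.08, glareSigmaMm = 25,
                          glareCoreSigmaMm = 1.5, penumbraSigmaMm = 1.5,
                          doseSpreadSigmaMm = 2, gain = 120, noiseRel = 0.01) {
  new("DetectorModel", sadCm = sadCm, sidCm = sidCm, muEffPerCm = muEffPerCm,
      hornCoeff = hornCoeff, oarCoeffs = oarCoeffs,
      glareWeights = glareWeights, glareSigmaMm = glareSigmaMm,
      glareCoreSigmaMm = glareCoreSigmaMm, penumbraSigmaMm = penumbraSigmaMm,
      doseSpreadSigmaMm = doseSpreadSigmaMm, gain = gain, noiseRel = noiseRel)
}

#' Construct a slab phantom
#'
#' @param thicknessesCm slab thicknesses, cm (total = sum).
#' @param lateralExtentCm numeric(2) crossline x inline extent, cm.
#' @param inserts optional insert list (see [PhantomSpec-class]).
#' @return A [PhantomSpec-class] centred on the isocentre.
#' @export
slabPhantom <- function(thicknessesCm, lateralExtentCm = c(40, 40),
                        inserts = list()) {
  new("PhantomSpec", slabThicknessesCm = thicknessesCm,
      lateralExtentCm = lateralExtentCm, inserts = inserts)
}

#' Thorax-like heterogeneous phantom
#'
#' A water block with two low-density lung boxes and a denser cord
#' cylinder. This is a stated synthetic stand-in for a commercial thorax
#' phantom whose exact geometry is proprietary.
#'
#' @param thicknessCm block thickness, cm.
#' @param lungDensity,cordDensity electron densities relative to water.
#' @return A [PhantomSpec-class].
#' @export
thoraxPhantom <- function(thicknessCm = 20, lungDensity = 0.25,
                          cordDensity = 1.1) {
  t2 <- thicknessCm * 10 / 2
  lung <- function(x1, x2) list(
    type = "box", x = c(x1, x2), depth = c(-0.6 * t2, 0.6 * t2),
    z = c(-120, 120), density = lungDensity)
  cord <- list(type = "cylinder", centre = c(0, 0.55 * t2), radius = 12,
               z = c(-150, 150), density = cordDensity)
  slabPhantom(thicknessCm, lateralExtentCm = c(40, 40),
              inserts = list(lung(-110, -30), lung(30, 110), cord))
}

#' Regular grid at the EPID plane
#'
#' @param nx,ny number of pixels (crossline, inline).
#' @param pitch pixel pitch, mm.
#' @return list with pixel-centre coordinate vectors `x`, `y` and `pitch`.
#' @export
epidGrid <- function(nx = 256L, ny = 192L, pitch = 400 / nx) {
  list(x = (seq_len(nx) - (nx + 1) / 2) * pitch,
       y = (seq_len(ny) - (ny + 1) / 2) * pitch,
       pitch = pitch)
}

# aperture openness (0/1) of one control point at arbitrary isocentre-plane
# coordinates; xi/yi are vectors defining a separable grid
.aperture_at <- function(cp, xi, yi) {
  bounds <- mlcLeafBoundaries()
  pair <- findInterval(yi, bounds, rightmost.closed = TRUE)
  pair[yi < bounds[1] | yi > bounds[61]] <- NA_integer_
  m <- matrix(0, length(xi), length(yi))
  xj <- xi > cp@jawX[1] & xi < cp@jawX[2]
  for (j in seq_along(yi)) {
    p <- pair[j]
    if (is.na(p) || yi[j] <= cp@jawY[1] || yi[j] >= cp@jawY[2]) next
    m[xj & xi > cp@mlcB[p] & xi < cp@mlcA[p], j] <- 1
  }
  m
}

#' Fluence of a zero-gantry beam at the EPID plane
#'
#' Accumulates the aperture over control-point intervals (trapezoidal
#' meterset weighting of the interval endpoints), blurs with the source
#' penumbra, applies the quadratic fluence horns, projects to the EPID
#' plane with magnification `sid/sad` and the per-ray inverse-square
#' factor, and scales by the beam MU.
#'
#' @param beam a zero-gantry [BeamField-class].
#' @param model a [DetectorModel-class].
#' @param grid an EPID-plane grid from [epidGrid()].
#' @return matrix of fluence (MU-weighted, arbitrary units).
#' @export
fluenceAtEpid <- function(beam, model, grid = epidGrid()) {
  stopifnot(is(beam, "BeamField"), is(model, "DetectorModel"))
  mag <- model@sidCm / model@sadCm
  xi <- grid$x / mag; yi <- grid$y / mag
  cps <- beam@controlPoints
  acc <- matrix(0, length(grid$x), length(grid$y))
  masks <- lapply(cps, .aperture_at, xi = xi, yi = yi)
  for (k in seq_len(length(cps) - 1L)) {
    dw <- cps[[k + 1L]]@weight - cps[[k]]@weight
    if (dw > 0) acc <- acc + dw * (masks[[k]] + masks[[k + 1L]]) / 2
  }
  sig_px <- model@penumbraSigmaMm * mag / grid$pitch
  acc <- cpp_gauss_blur(acc, sig_px, sig_px)
  sid_mm <- model@sidCm * 10
  horn <- 1 + model@hornCoeff * outer(xi, yi, function(x, y) (x^2 + y^2)) / 200^2
  invsq <- (model@sadCm * 10)^2 /
    (sid_mm^2 + outer(grid$x, grid$y, function(x, y) x^2 + y^2))
  beam@monitorUnits * acc * horn * invsq
}

# water-equivalent radiological path (mm) from the source to each EPID
# pixel through the phantom: the slab stack is a density-1 box; inserts
# add (density - 1) times their chord. Setup shifts and the phantom
# rotation (from gantry-offset errors) are applied to the geometry.
.radiological_path <- function(phantom, model, grid) {
  sad <- model@sadCm * 10; sid <- model@sidCm * 10
  X <- outer(grid$x, rep(1, length(grid$y)))
  Y <- outer(rep(1, length(grid$x)), grid$y)
  # ray from source s = (0, -sad) to EPID pixel e = (X, sid - sad) in the
  # (crossline, depth-below-iso) plane; inline is linear in the same t
  rot <- -phantom@rotationDeg * pi / 180  # intersect in unrotated phantom frame
  co <- cos(rot); si <- sin(rot)
  sx <- -si * (-sad) + 0 * X; sd_ <- co * (-sad) + 0 * X
  ex <- co * X - si * (sid - sad); ed <- si * X + co * (sid - sad)
  dx <- ex - sx; dd <- ed - sd_; dyl <- Y       # inline from 0 to Y
  L <- sqrt(dx^2 + dd^2 + dyl^2)                # full segment length, mm
  t_box <- function(lo, hi, s, d) {
    # per-axis parameter interval of s + t d inside [lo, hi]
    t1 <- (lo - s) / d; t2 <- (hi - s) / d
    deg <- abs(d) < 1e-12
    tlo <- pmin(t1, t2); thi <- pmax(t1, t2)
    tlo[deg] <- ifelse(s[deg] >= lo & s[deg] <= hi, -Inf, Inf)
    thi[deg] <- ifelse(s[deg] >= lo & s[deg] <= hi, Inf, -Inf)
    list(lo = tlo, hi = thi)
  }
  chord_box <- function(xr, dr, zr) {
    ix <- t_box(xr[1], xr[2], sx, dx)
    id_ <- t_box(dr[1], dr[2], sd_, dd)
    iz <- t_box(zr[1], zr[2], 0 * Y, dyl)
    tlo <- pmax(ix$lo, id_$lo, iz$lo, 0)
    thi <- pmin(ix$hi, id_$hi, iz$hi, 1)
    pmax(thi - tlo, 0) * L
  }
  T0 <- sum(phantom@slabThicknessesCm) * 10
  v <- phantom@verticalShiftMm; h <- phantom@lateralShiftMm
  ex_mm <- phantom@lateralExtentCm * 10
  path <- chord_box(c(-ex_mm[1] / 2, ex_mm[1] / 2) + h,
                    c(-T0 / 2 - phantom@addedTopCm * 10, T0 / 2) - v,
                    c(-ex_mm[2] / 2, ex_mm[2] / 2))
  for (ins in phantom@inserts) {
    w <- ins$density - 1
    if (ins$type == "box") {
      path <- path + w * chord_box(ins$x + h, ins$depth - v, ins$z)
    } else if (ins$type == "cylinder") {
      # quadratic |(x, d)(t) - c| = r in the (crossline, depth) plane
      cx <- ins$centre[1] + h; cd <- ins$centre[2] - v
      a <- dx^2 + dd^2
      b <- 2 * ((sx - cx) * dx + (sd_ - cd) * dd)
      cc <- (sx - cx)^2 + (sd_ - cd)^2 - ins$radius^2
      disc <- b^2 - 4 * a * cc
      hit <- disc > 0
      sq <- sqrt(pmax(disc, 0))
      tlo <- thi <- 0 * X
      tlo[hit] <- ((-b - sq) / (2 * a))[hit]
      thi[hit] <- ((-b + sq) / (2 * a))[hit]
      iz <- t_box(ins$z[1], ins$z[2], 0 * Y, dyl)
      seg <- pmax(pmin(thi, iz$hi, 1) - pmax(tlo, iz$lo, 0), 0)
      path <- path + w * seg * L * hit
    } else stop("unknown insert type: ", ins$type)
  }
  path
}

#' Simulate the noisy water-dose map at the equivalent-EPID plane
#'
#' Dose = fluence x exp(-mu_eff x radiological path), convolved with a
#' small in-water spread, plus heteroscedastic Gaussian noise with
#' sd = `noiseRel` x sqrt(D x Dmax) emulating Monte-Carlo statistical
#' uncertainty. Fully reproducible from `seed`.
#'
#' @param beam a zero-gantry [BeamField-class].
#' @param phantom a [PhantomSpec-class].
#' @param model a [DetectorModel-class].
#' @param error optional [ErrorSpec-class] injected before simulation.
#' @param seed optional integer seed for the noise.
#' @param grid EPID-plane grid from [epidGrid()].
#' @param noise logical; set `FALSE` for the noiseless dose.
#' @return A [PlanarDose-class] at 50 cm below the isocentre.
#' @export
waterDose <- function(beam, phantom, model, error = NULL, seed = NULL,
                      grid = epidGrid(), noise = TRUE) {
  if (!is.null(error)) {
    pert <- injectError(beam, phantom, error)
    beam <- pert$beam; phantom <- pert$phantom
  }
  flu <- fluenceAtEpid(beam, model, grid)
  att <- exp(-model@muEffPerCm / 10 * .radiological_path(phantom, model, grid))
  d <- flu * att
  sig_px <- model@doseSpreadSigmaMm / grid$pitch
  d <- cpp_gauss_blur(d, sig_px, sig_px)
  if (noise && model@noiseRel > 0) {
    if (!is.null(seed)) set.seed(seed)
    d <- d + stats::rnorm(length(d), 0,
                          model@noiseRel * sqrt(pmax(d, 0) * max(d)))
    d <- matrix(pmax(d, 0), nrow(d), ncol(d))
  }
  planarDose(d, spacing = c(grid$pitch, grid$pitch))
}

#' Ground-truth detector response: noiseless dose to transmission image
#'
#' `TI = gain x oar(r) x (glare kernel (*) dose)`, cropped and resampled to
#' the analysis grid. The glare kernel is a normalized mixture of a narrow
#' core and broad Gaussians; `oar(r)` is the radial off-axis response
#' polynomial. The transform is deliberately not a global scaling: it is
#' what the network has to learn.
#'
#' @param dose a noiseless [PlanarDose-class].
#' @param model a [DetectorModel-class].
#' @param nx,ny analysis-grid size.
#' @return A [TransmissionImage-class] with provenance `"synthetic"`.
#' @export
trueResponse <- function(dose, model, nx = 256L, ny = 192L) {
  stopifnot(is(dose, "PlanarDose"))
  v <- dose@values
  w_tail <- model@glareWeights
  w0 <- 1 - sum(w_tail)
  px <- dose@spacing[1]; py <- dose@spacing[2]
  g <- w0 * cpp_gauss_blur(v, model@glareCoreSigmaMm / px,
                           model@glareCoreSigmaMm / py)
  for (k in seq_along(w_tail))
    g <- g + w_tail[k] * cpp_gauss_blur(v, model@glareSigmaMm[k] / px,
                                        model@glareSigmaMm[k] / py)
  d <- dim(v)
  xs <- dose@origin[1] + (seq_len(d[1]) - (d[1] + 1) / 2) * px
  ys <- dose@origin[2] + (seq_len(d[2]) - (d[2] + 1) / 2) * py
  u <- outer(xs^2, ys^2, "+") / 100^2
  oar <- matrix(1, d[1], d[2])
  for (k in seq_along(model@oarCoeffs)) oar <- oar + model@oarCoeffs[k] * u^k
  oar <- pmax(oar, 0.05)
  ti <- cropResample(planarDose(model@gain * oar * g, dose@spacing,
                                dose@origin, dose@planeDepthCm),
                     nx = nx, ny = ny)
  ti@provenance <- "synthetic"
  ti
}

# ---------------------------------------------------------------------------
# Error injection
# ---------------------------------------------------------------------------

#' Construct an error specification
#'
#' @param kind error kind (see [ErrorSpec-class]).
#' @param magnitude percent, mm or degrees depending on kind.
#' @param label short label (defaults to `kind`).
#' @return An [ErrorSpec-class].
#' @export
errorSpec <- function(kind, magnitude, label = kind) {
  new("ErrorSpec", kind = kind, magnitude = as.numeric(magnitude),
      label = label)
}

#' The 21-error sensitivity protocol
#'
#' Dose errors Ea1-Ea5 (MU +1, +3, +5, +10, -5 %), lateral setup shifts
#' Eb1-Eb3 (5, 10, 20 mm towards the patient's right), anterior shifts
#' Eb4-Eb6 (5, 10, 20 mm), gantry offsets Ec1-Ec2 (+5, +10 degrees), MLC
#' errors Ed1-Ed4 (all leaves opened 5 mm; both banks shifted 2 mm; in-field
#' bank-B leaves shifted 5 mm; central four pairs opened 10 mm), and added
#' solid water Ee1-Ee4 (5, 10, 20, 30 mm on top).
#'
#' @return named list of [ErrorSpec-class] objects keyed by label.
#' @export
sensitivityErrorSpecs <- function() {
  sp <- list(
    errorSpec("mu_scale", 1, "Ea1"), errorSpec("mu_scale", 3, "Ea2"),
    errorSpec("mu_scale", 5, "Ea3"), errorSpec("mu_scale", 10, "Ea4"),
    errorSpec("mu_scale", -5, "Ea5"),
    errorSpec("iso_shift_lateral", 5, "Eb1"),
    errorSpec("iso_shift_lateral", 10, "Eb2"),
    errorSpec("iso_shift_lateral", 20, "Eb3"),
    errorSpec("iso_shift_anterior", 5, "Eb4"),
    errorSpec("iso_shift_anterior", 10, "Eb5"),
    errorSpec("iso_shift_anterior", 20, "Eb6"),
    errorSpec("gantry_offset", 5, "Ec1"), errorSpec("gantry_offset", 10, "Ec2"),
    errorSpec("mlc_open_all", 5, "Ed1"), errorSpec("mlc_bank_shift", 2, "Ed2"),
    errorSpec("mlc_bankB_infield_shift", 5, "Ed3"),
    errorSpec("mlc_central4_open", 10, "Ed4"),
    errorSpec("slab_add", 5, "Ee1"), errorSpec("slab_add", 10, "Ee2"),
    errorSpec("slab_add", 20, "Ee3"), errorSpec("slab_add", 30, "Ee4"))
  names(sp) <- vapply(sp, function(e) e@label, character(1))
  sp
}

#' Inject a delivery or setup error into a beam/phantom pair
#'
#' One error at a time. MU scaling multiplies the beam MU; lateral/anterior
#' shifts translate the phantom relative to the beam; a gantry offset is
#' emulated by rotating the phantom by minus the offset; MLC errors edit
#' the leaf banks on every control point; `slab_add` stacks extra solid
#' water on top (the source side) of the phantom.
#'
#' @param beam a [BeamField-class].
#' @param phantom a [PhantomSpec-class].
#' @param error an [ErrorSpec-class].
#' @return list with the perturbed `beam` and `phantom`.
#' @export
injectError <- function(beam, phantom, error) {
  stopifnot(is(error, "ErrorSpec"))
  m <- error@magnitude
  edit_cps <- function(f) {
    beam@controlPoints <- lapply(beam@controlPoints, f)
    beam
  }
  switch(error@kind,
    mu_scale = { beam@monitorUnits <- beam@monitorUnits * (1 + m / 100) },
    iso_shift_lateral = { phantom@lateralShiftMm <- phantom@lateralShiftMm - m },
    iso_shift_anterior = { phantom@verticalShiftMm <- phantom@verticalShiftMm + m },
    gantry_offset = { phantom@rotationDeg <- phantom@rotationDeg - m },
    mlc_open_all = {
      beam <- edit_cps(function(cp) {
        cp@mlcA <- pmin(cp@mlcA + m / 2, 200)
        cp@mlcB <- pmax(cp@mlcB - m / 2, -200)
        cp
      })
    },
    mlc_bank_shift = {
      beam <- edit_cps(function(cp) {
        cp@mlcA <- pmin(pmax(cp@mlcA + m, -200), 200)
        cp@mlcB <- pmin(pmax(cp@mlcB + m, -200), 200)
        cp
      })
    },
    mlc_bankB_infield_shift = {
      beam <- edit_cps(function(cp) {
        infield <- (cp@mlcA - cp@mlcB) > 0.5
        cp@mlcB[infield] <- pmax(cp@mlcB[infield] - m, -200)
        cp
      })
    },
    mlc_central4_open = {
      beam <- edit_cps(function(cp) {
        ctr <- 29:32
        cp@mlcA[ctr] <- pmin(cp@mlcA[ctr] + m / 2, 200)
        cp@mlcB[ctr] <- pmax(cp@mlcB[ctr] - m / 2, -200)
        cp
      })
    },
    slab_add = { phantom@addedTopCm <- phantom@addedTopCm + m / 10 },
    stop("unknown error kind: ", error@kind))
  list(beam = beam, phantom = phantom)
}

# ---------------------------------------------------------------------------
# Dataset assembly
# ---------------------------------------------------------------------------

# one (noisy input, noiseless target) pair; fluence computed once
.simulate_pair <- function(beam, phantom, model, doseGrid, nx, ny) {
  clean <- waterDose(beam, phantom, model, grid = doseGrid, noise = FALSE)
  noisy <- clean@values
  noisy <- noisy + stats::rnorm(length(noisy), 0,
                                model@noiseRel * sqrt(pmax(noisy, 0) * max(noisy)))
  noisy <- matrix(pmax(noisy, 0), nrow(noisy), ncol(noisy))
  input <- cropResample(planarDose(noisy, clean@spacing), nx = nx, ny = ny)
  target <- trueResponse(clean, model, nx = nx, ny = ny)
  list(input = input@values, target = target@values)
}

#' Generate a paired synthetic dose-to-image dataset
#'
#' Samples random multi-segment static fields (2-12 segments, stepped
#' rectangular apertures up to 20 cm x 20 cm at the isocentre plane) on
#' random phantoms (slab thicknesses from the standard 3-24 cm set, with a
#' configurable fraction of thorax-like heterogeneous phantoms), simulates
#' the noisy water dose as network input and the noiseless detector
#' response as target, and splits the pairs into disjoint
#' train/validation/test sets. Bit-reproducible from `seed`.
#'
#' @param splitSizes integer(3) train/val/test sizes.
#' @param nx,ny analysis-grid size (4:3 aspect).
#' @param model a [DetectorModel-class].
#' @param seed integer seed.
#' @param sampler list of overrides: `segments` (range, default 2-12),
#'   `maxFieldMm` (200), `stepSdMm` (3), `thicknessesCm` (3, 5, 8, 10, 12,
#'   15, 18, 20, 24), `thoraxProb` (1/3), `doseMarginPx` (8).
#' @return A [DatasetBundle-class].
#' @export
generateDataset <- function(splitSizes = c(1200L, 150L, 150L),
                            nx = 256L, ny = 192L,
                            model = detectorModel(), seed = 1L,
                            sampler = list()) {
  cfg <- utils::modifyList(
    list(segments = c(2L, 12L), maxFieldMm = 200, stepSdMm = 3,
         thicknessesCm = c(3, 5, 8, 10, 12, 15, 18, 20, 24),
         thoraxProb = 1 / 3, doseMarginPx = 8L), sampler)
  n <- sum(splitSizes)
  if (n < 1L) stop("nothing to generate: split sizes sum to 0")
  pitch <- 400 / nx
  dg <- epidGrid(nx + 2L * cfg$doseMarginPx, ny + 2L * cfg$doseMarginPx, pitch)
  set.seed(seed)
  inputs <- targets <- vector("list", n)
  meta <- data.frame(field = seq_len(n), segments = NA_integer_,
                     thicknessCm = NA_real_, thorax = NA, mu = NA_real_)
  for (i in seq_len(n)) {
    nseg <- sample(seq(cfg$segments[1], cfg$segments[2]), 1)
    beam <- randomBeam(sprintf("F%04d", i), nSegments = nseg,
                       maxFieldMm = cfg$maxFieldMm, stepSdMm = cfg$stepSdMm)
    thorax <- stats::runif(1) < cfg$thoraxProb
    th <- sample(cfg$thicknessesCm, 1)
    phantom <- if (thorax) thoraxPhantom(max(th, 12)) else slabPhantom(th)
    pair <- .simulate_pair(beam, phantom, model, dg, nx, ny)
    inputs[[i]] <- pair$input; targets[[i]] <- pair$target
    meta$segments[i] <- nseg
    meta$thicknessCm[i] <- sum(phantom@slabThicknessesCm)
    meta$thorax[i] <- thorax
    meta$mu[i] <- beam@monitorUnits
  }
  idx <- seq_len(n)
  new("DatasetBundle", inputs = inputs, targets = targets, meta = meta,
      splitTrain = idx[seq_len(splitSizes[1])],
      splitVal = idx[splitSizes[1] + seq_len(splitSizes[2])],
      splitTest = idx[splitSizes[1] + splitSizes[2] + seq_len(splitSizes[3])],
      seed = as.integer(seed), pixelPitch = c(pitch, pitch))
}
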