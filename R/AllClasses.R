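#' @import methods
NULL

# ---------------------------------------------------------------------------
# Delivery geometry
# ---------------------------------------------------------------------------

#' Single MLC/jaw control point of an IMRT beam
#'
#' A control point records the machine state at one instant of a static-gantry
#' IMRT delivery: the 60 leaf-edge positions of each MLC bank (Millennium 120
#' layout), the jaw positions, the cumulative meterset weight and the gantry
#' angle. All positions are in mm projected to the isocentre plane, IEC 61217
#' crossline axis; bank-B edges sit on the negative-crossline side of the
#' aperture so the leaf-pair gap is `mlcA - mlcB`.
#'
#' @slot index integer control-point index (0-based, as in DICOM).
#' @slot weight cumulative meterset weight in `[0, 1]`.
#' @slot mlcA,mlcB numeric(60) leaf-edge positions (mm at isocentre).
#' @slot jawX,jawY numeric(2) jaw positions `(x1, x2)` / `(y1, y2)` in mm.
#' @slot gantry gantry angle in degrees, `[0, 360)`.
#' @exportClass ControlPoint
setClass("ControlPoint",
  representation(index = "integer", weight = "numeric",
                 mlcA = "numeric", mlcB = "numeric",
                 jawX = "numeric", jawY = "numeric", gantry = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@mlcA) != 60L || length(object@mlcB) != 60L)
      msg <- c(msg, "mlcA and mlcB must each hold 60 leaf positions")
    if (length(object@weight) != 1L || object@weight < -1e-9 || object@weight > 1 + 1e-9)
      msg <- c(msg, "cumulative meterset weight must lie in [0, 1]")
    if (any(object@mlcB > object@mlcA + 1e-6))
      msg <- c(msg, "bank-B edges must not pass bank-A edges (closed pairs allowed)")
    if (length(object@jawX) != 2L || length(object@jawY) != 2L ||
        object@jawX[1] > object@jawX[2] || object@jawY[1] > object@jawY[2])
      msg <- c(msg, "jaws must be (low, high) pairs in mm")
    if (object@gantry < 0 || object@gantry >= 360)
      msg <- c(msg, "gantry angle must be in [0, 360)")
    if (length(msg)) msg else TRUE
  })

#' One beam (field) of a treatment plan
#'
#' @slot beamId character beam identifier (unique within a plan).
#' @slot monitorUnits delivered monitor units (MU > 0).
#' @slot controlPoints ordered list of [ControlPoint-class] objects.
#' @slot originalGantryAngle gantry angle of the source plan in degrees;
#'   preserved when the plan is zero-gantry split.
#' @exportClass BeamField
setClass("BeamField",
  representation(beamId = "character", monitorUnits = "numeric",
                 controlPoints = "list", originalGantryAngle = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@controlPoints) < 2L)
      msg <- c(msg, "a beam needs at least 2 control points")
    if (!all(vapply(object@controlPoints, is, logical(1), "ControlPoint")))
      msg <- c(msg, "controlPoints must all be ControlPoint objects")
    else {
      w <- vapply(object@controlPoints, function(cp) cp@weight, numeric(1))
      if (any(diff(w) < -1e-9)) msg <- c(msg, "cumulative meterset weights must be non-decreasing")
      if (abs(w[1]) > 1e-9 || abs(w[length(w)] - 1) > 1e-9)
        msg <- c(msg, "cumulative meterset weight must start at 0 and end at 1")
      g <- vapply(object@controlPoints, function(cp) cp@gantry, numeric(1))
      if (diff(range(g)) > 1e-6)
        msg <- c(msg, "gantry angle must be static within a beam (IMRT only)")
    }
    if (!is.finite(object@monitorUnits) || object@monitorUnits <= 0)
      msg <- c(msg, "monitorUnits must be > 0")
    if (length(msg)) msg else TRUE
  })

#' A treatment plan: an ordered set of static-gantry IMRT beams
#'
#' @slot planId character plan label.
#' @slot machine character treatment machine name.
#' @slot beams list of [BeamField-class] objects with unique ids.
#' @exportClass TreatmentPlan
setClass("TreatmentPlan",
  representation(planId = "character", machine = "character", beams = "list"),
  validity = function(object) {
    msg <- character()
    if (length(object@beams) < 1L) msg <- c(msg, "a plan needs at least one beam")
    if (!all(vapply(object@beams, is, logical(1), "BeamField")))
      msg <- c(msg, "beams must all be BeamField objects")
    else {
      ids <- vapply(object@beams, function(b) b@beamId, character(1))
      if (anyDuplicated(ids)) msg <- c(msg, "beam ids must be unique")
    }
    if (length(msg)) msg else TRUE
  })

# ---------------------------------------------------------------------------
# CT volumes
# ---------------------------------------------------------------------------

#' A CT volume on a regular grid
#'
#' Voxels are stored as a 3D array indexed `[x, y, z]` with x the crossline
#' axis (patient left positive), y the beam axis at gantry 0 (depth below the
#' isocentre positive, i.e. posterior for a supine patient), and z the inline
#' (superior-inferior) axis. `origin` is the patient-coordinate position (mm)
#' of the centre of voxel `[1, 1, 1]`.
#'
#' @slot voxels 3D array of Hounsfield units.
#' @slot spacing numeric(3) voxel spacing in mm.
#' @slot origin numeric(3) position of the first voxel centre in mm.
#' @slot isocentre numeric(3) isocentre position in mm (the coordinate origin
#'   of the delivery geometry).
#' @exportClass CTVolume
setClass("CTVolume",
  representation(voxels = "array", spacing = "numeric", origin = "numeric",
                 isocentre = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@voxels)) != 3L) msg <- c(msg, "voxels must be a 3D array")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
      msg <- c(msg, "spacing must be three positive mm values")
    if (length(object@origin) != 3L || length(object@isocentre) != 3L)
      msg <- c(msg, "origin and isocentre must be mm triples")
    rng <- range(object@voxels)
    if (rng[1] < -1024 - 1e-6 || rng[2] > 3071 + 1e-6)
      msg <- c(msg, "HU values must lie in [-1024, 3071]")
    if (length(msg)) msg else TRUE
  })

#' A combined CT: plan CT plus equivalent-EPID solid-water slab
#'
#' Produced by [insertSolidWater()] / [buildCombinedCT()]: the plan CT after
#' couch HU substitution, axial counter-rotation by the gantry angle and axial
#' extension, with a 5 cm solid-water slab (HU 0) whose top face sits 47 cm
#' below the isocentre and an air gap (HU -1000) between the patient/couch and
#' the slab. The scoring plane 50 cm below the isocentre then lies 3 cm deep
#' in the slab, the upstream 3 cm acting as build-up.
#'
#' @slot slabRecord list with `top_depth_cm`, `thickness_cm`, `hu`,
#'   `lateral_mm` describing the inserted slab.
#' @slot gapHU HU assigned to the air gap (-1000).
#' @slot rotationAppliedDeg anti-clockwise axial rotation applied, degrees.
#' @exportClass CombinedCT
setClass("CombinedCT", contains = "CTVolume",
  representation(slabRecord = "list", gapHU = "numeric",
                 rotationAppliedDeg = "numeric"))

#' A 3D dose grid sharing the CTVolume geometry conventions
#'
#' @slot values 3D array of dose (arbitrary consistent units, >= 0).
#' @slot spacing,origin,isocentre as in [CTVolume-class].
#' @exportClass DoseVolume
setClass("DoseVolume",
  representation(values = "array", spacing = "numeric", origin = "numeric",
                 isocentre = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@values)) != 3L) msg <- c(msg, "values must be a 3D array")
    if (any(!is.finite(object@values)) || any(object@values < 0))
      msg <- c(msg, "dose must be finite and non-negative")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
      msg <- c(msg, "spacing must be three positive mm values")
    if (length(msg)) msg else TRUE
  })

# ---------------------------------------------------------------------------
# Planar images at the equivalent-EPID plane
# ---------------------------------------------------------------------------

#' A 2D dose plane at the equivalent-EPID level
#'
#' `values[i, j]` indexes crossline (i) by inline (j); `origin` is the mm
#' offset of the grid centre from the beam-axis piercing point so that pixel
#' centres sit at `origin + (index - (n + 1) / 2) * spacing`.
#'
#' @slot values 2D matrix of dose (arbitrary consistent units).
#' @slot spacing numeric(2) pixel pitch (mm crossline, mm inline).
#' @slot origin numeric(2) offset of grid centre from the beam axis, mm.
#' @slot planeDepthCm depth of the plane below the isocentre, cm (50).
#' @exportClass PlanarDose
setClass("PlanarDose",
  representation(values = "matrix", spacing = "numeric", origin = "numeric",
                 planeDepthCm = "numeric"),
  prototype(planeDepthCm = 50, origin = c(0, 0)),
  validity = function(object) {
    msg <- character()
    if (any(!is.finite(object@values)) || any(object@values < -1e-9))
      msg <- c(msg, "dose values must be finite and non-negative")
    if (length(object@spacing) != 2L || any(object@spacing <= 0))
      msg <- c(msg, "spacing must be two positive mm values")
    if (length(msg)) msg else TRUE
  })

#' An EPID transmission image on the analysis grid
#'
#' The analysis grid covers the 40 cm x 30 cm panel area centred on the beam
#' axis. At full scale it is 256 x 192 (1.5625 mm pitch, i.e. 400/256 mm);
#' scaled-down profiles keep the 4:3 aspect so both axes share one pitch.
#' `values[i, j]` indexes crossline by inline.
#'
#' @slot values 2D matrix (greyscale, continuous, >= 0).
#' @slot pixelPitch numeric(2) pitch in mm, `(400/ncol_x, 300/ncol_y)`.
#' @slot provenance one of `"measured"`, `"predicted"`, `"synthetic"`.
#' @exportClass TransmissionImage
setClass("TransmissionImage",
  representation(values = "matrix", pixelPitch = "numeric",
                 provenance = "character"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@values)
    if (d[1] * 3L != d[2] * 4L)
      msg <- c(msg, "analysis grid must keep the 4:3 (40 cm x 30 cm) aspect")
    if (length(object@pixelPitch) != 2L || any(object@pixelPitch <= 0))
      msg <- c(msg, "pixelPitch must be two positive mm values")
    else if (abs(object@pixelPitch[1] - object@pixelPitch[2]) > 1e-9)
      msg <- c(msg, "pixel pitch must be isotropic on the analysis grid")
    if (any(!is.finite(object@values)) || any(object@values < -1e-9))
      msg <- c(msg, "greyscale values must be finite and non-negative")
    if (!object@provenance %in% c("measured", "predicted", "synthetic"))
      msg <- c(msg, "provenance must be measured, predicted or synthetic")
    if (length(msg)) msg else TRUE
  })

# ---------------------------------------------------------------------------
# Synthetic detector model, phantoms and errors
# ---------------------------------------------------------------------------

#' Parametric phantom for the synthetic detector simulator
#'
#' A stack of solid-water slabs centred on the isocentre (half the total
#' thickness above, half below), 40 cm x 40 cm laterally by default, with
#' optional low/high-density inserts for a thorax-like geometry and setup
#' shift parameters used by the error-injection protocol.
#'
#' @slot slabThicknessesCm numeric vector of slab thicknesses (cm); the total
#'   radiological thickness is their sum.
#' @slot lateralExtentCm numeric(2) crossline x inline extent, cm.
#' @slot inserts list of inserts; each is a list with `type` ("box" or
#'   "cylinder"), geometry in phantom coordinates (mm, see vignette) and
#'   `density` (electron density relative to water).
#' @slot lateralShiftMm,verticalShiftMm setup offsets in mm (lateral =
#'   crossline, vertical = along the beam axis / anterior direction).
#' @slot rotationDeg rotation of the phantom about the inline axis, degrees
#'   (used to emulate gantry-offset errors by counter-rotating the phantom).
#' @slot addedTopCm extra solid water stacked on the source side, cm.
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(slabThicknessesCm = "numeric", lateralExtentCm = "numeric",
                 inserts = "list", lateralShiftMm = "numeric",
                 verticalShiftMm = "numeric", rotationDeg = "numeric",
                 addedTopCm = "numeric"),
  prototype(lateralExtentCm = c(40, 40), inserts = list(),
            lateralShiftMm = 0, verticalShiftMm = 0, rotationDeg = 0,
            addedTopCm = 0),
  validity = function(object) {
    msg <- character()
    if (any(object@slabThicknessesCm < 0)) msg <- c(msg, "thickness must be >= 0")
    dens <- vapply(object@inserts, function(i) i$density, numeric(1))
    if (length(dens) && any(dens <= 0)) msg <- c(msg, "insert densities must be > 0")
    if (length(msg)) msg else TRUE
  })

#' Parametric ground-truth dose-to-greyscale detector transform
#'
#' Encodes how the synthetic EPID signal differs from the water dose at the
#' equivalent-EPID plane: a radially declining off-axis response (the
#' flood-field calibration removes the beam "horns" from the image but not
#' from the dose), a two-Gaussian glare kernel, a global gain, plus the beam
#' model used to simulate the dose itself (effective attenuation, fluence
#' horns, source penumbra, in-water spread, MC-like noise amplitude).
#'
#' @slot sadCm source-axis distance, cm (100).
#' @slot sidCm source-imager distance, cm (150; EPID 50 cm below isocentre).
#' @slot muEffPerCm effective linear attenuation of 6 MV in water, 1/cm.
#' @slot hornCoeff quadratic fluence-horn amplitude at 20 cm off-axis
#'   (isocentre scale).
#' @slot oarCoeffs polynomial coefficients of the detector off-axis response
#'   in `u = (r_epid / 100 mm)^2`: `oar(r) = 1 + c1 u + c2 u^2 + ...`.
#' @slot glareWeights,glareSigmaMm weights and sigmas (mm at the EPID plane)
#'   of the long-range glare Gaussians; the remaining `1 - sum(weights)` is a
#'   narrow core of width `glareCoreSigmaMm`.
#' @slot glareCoreSigmaMm core blur sigma, mm.
#' @slot penumbraSigmaMm source blur sigma at the isocentre plane, mm.
#' @slot doseSpreadSigmaMm lateral in-water dose spread at the EPID plane, mm.
#' @slot gain dose-to-greyscale scale factor.
#' @slot noiseRel relative MC noise amplitude at maximum dose.
#' @exportClass DetectorModel
setClass("DetectorModel",
  representation(sadCm = "numeric", sidCm = "numeric", muEffPerCm = "numeric",
                 hornCoeff = "numeric", oarCoeffs = "numeric",
                 glareWeights = "numeric", glareSigmaMm = "numeric",
                 glareCoreSigmaMm = "numeric", penumbraSigmaMm = "numeric",
                 doseSpreadSigmaMm = "numeric", gain = "numeric",
                 noiseRel = "numeric"),
  validity = function(object) {
    msg <- character()
    if (any(object@glareWeights < 0) || sum(object@glareWeights) > 1)
      msg <- c(msg, "glare tail weights must be >= 0 and sum to <= 1")
    if (any(object@glareSigmaMm <= 0) || object@glareCoreSigmaMm <= 0)
      msg <- c(msg, "glare sigmas must be > 0")
    if (length(object@glareWeights) != length(object@glareSigmaMm))
      msg <- c(msg, "glareWeights and glareSigmaMm must have equal length")
    if (object@gain <= 0) msg <- c(msg, "gain must be > 0")
    if (object@sadCm <= 0 || object@sidCm <= object@sadCm)
      msg <- c(msg, "need 0 < sadCm < sidCm")
    if (length(msg)) msg else TRUE
  })

#' A deliberately introduced delivery or setup error
#'
#' @slot kind one of `mu_scale`, `iso_shift_lateral`, `iso_shift_anterior`,
#'   `gantry_offset`, `mlc_open_all`, `mlc_bank_shift`,
#'   `mlc_bankB_infield_shift`, `mlc_central4_open`, `slab_add`.
#' @slot magnitude percent (mu_scale), mm (shifts, MLC, slab_add) or degrees
#'   (gantry_offset).
#' @slot label short label, e.g. `"Ea3"`.
#' @exportClass ErrorSpec
setClass("ErrorSpec",
  representation(kind = "character", magnitude = "numeric", label = "character"),
  validity = function(object) {
    kinds <- c("mu_scale", "iso_shift_lateral", "iso_shift_anterior",
               "gantry_offset", "mlc_open_all", "mlc_bank_shift",
               "mlc_bankB_infield_shift", "mlc_central4_open", "slab_add")
    if (!object@kind %in% kinds)
      return(sprintf("unknown error kind '%s'", object@kind))
    TRUE
  })

#' A paired dose-to-image dataset with train/validation/test split
#'
#' @slot inputs list of input matrices (noisy water-dose maps resampled to
#'   the analysis grid).
#' @slot targets list of target matrices (noiseless synthetic transmission
#'   images on the same grid).
#' @slot meta data.frame of per-field metadata (segments, phantom, MU, ...).
#' @slot splitTrain,splitVal,splitTest disjoint index vectors.
#' @slot seed integer seed the bundle was generated from.
#' @slot pixelPitch numeric(2) analysis-grid pitch in mm.
#' @exportClass DatasetBundle
setClass("DatasetBundle",
  representation(inputs = "list", targets = "list", meta = "data.frame",
                 splitTrain = "integer", splitVal = "integer",
                 splitTest = "integer", seed = "integer",
                 pixelPitch = "numeric"),
  validity = function(object) {
    msg <- character()
    idx <- c(object@splitTrain, object@splitVal, object@splitTest)
    if (anyDuplicated(idx)) msg <- c(msg, "splits must be disjoint")
    if (length(idx) && max(idx) > length(object@inputs))
      msg <- c(msg, "split indices out of range")
    if (length(object@inputs) != length(object@targets))
      msg <- c(msg, "inputs and targets must pair up")
    if (length(msg)) msg else TRUE
  })

# ---------------------------------------------------------------------------
# Network
# ---------------------------------------------------------------------------

#' U-net architecture description
#'
#' Encoder of `depth` blocks (two 3x3 same-padded convolutions + ReLU, then
#' 2x2 max pooling), mirrored decoder (2x2 nearest upsampling, skip
#' concatenation, two 3x3 convolutions), a final 1x1 projection, and the
#' network input added to the projection output (residual output).
#'
#' @slot depth number of encoder blocks / poolings.
#' @slot baseChannels channels of the first encoder block; doubled per level.
#' @slot height,width input grid size (crossline x inline); both must be
#'   divisible by `2^depth`.
#' @exportClass NetworkSpec
setClass("NetworkSpec",
  representation(depth = "integer", baseChannels = "integer",
                 height = "integer", width = "integer"),
  validity = function(object) {
    f <- 2L^object@depth
    if (object@height %% f != 0L || object@width %% f != 0L)
      return(sprintf("input %d x %d not divisible by 2^depth = %d",
                     object@height, object@width, f))
    if (object@baseChannels < 1L) return("baseChannels must be >= 1")
    TRUE
  })

#' Training recipe for the response network
#'
#' @slot learningRate Adam learning rate.
#' @slot lrDecayAt integer epochs at which the learning rate is halved
#'   (empty = constant rate throughout).
#' @slot batchSize mini-batch size.
#' @slot epochs number of passes over the training split.
#' @slot seed integer seed for weight init and batch shuffling.
#' @slot doseScale,tiScale fixed scaling constants dividing network inputs
#'   and targets; computed from the training split and stored with the model.
#' @exportClass TrainSpec
setClass("TrainSpec",
  representation(learningRate = "numeric", lrDecayAt = "integer",
                 batchSize = "integer",
                 epochs = "integer", seed = "integer",
                 doseScale = "numeric", tiScale = "numeric"),
  prototype(lrDecayAt = integer(0)),
  validity = function(object) {
    if (object@epochs < 1L || object@batchSize < 1L)
      return("epochs and batchSize must be positive")
    TRUE
  })

#' A trained dose-to-image network with its scaling constants
#'
#' @slot weights list of weight arrays as returned by the training backend.
#' @slot networkSpec the [NetworkSpec-class] used.
#' @slot trainSpec the [TrainSpec-class] used (with scaling constants filled).
#' @slot lossHistory data.frame with `epoch`, `train`, `val` MSE (scaled
#'   units), one row per epoch run.
#' @exportClass TrainedModel
setClass("TrainedModel",
  representation(weights = "list", networkSpec = "NetworkSpec",
                 trainSpec = "TrainSpec", lossHistory = "data.frame"),
  validity = function(object) {
    if (nrow(object@lossHistory) != object@trainSpec@epochs)
      return("loss history length must equal epochs run")
    TRUE
  })

# ---------------------------------------------------------------------------
# Gamma analysis
# ---------------------------------------------------------------------------

#' Global 2D gamma criteria
#'
#' @slot dosePercent dose-difference criterion, % of the global normalization
#'   (the reference-image maximum).
#' @slot dtaMm distance-to-agreement criterion, mm.
#' @slot thresholdPercent low-dose threshold, % of the reference maximum;
#'   reference points below it are excluded from the analysis.
#' @slot searchRadiusFactor search radius as a multiple of dtaMm.
#' @slot interpStep sub-pixel interpolation step as a fraction of dtaMm.
#' @exportClass GammaCriteria
setClass("GammaCriteria",
  representation(dosePercent = "numeric", dtaMm = "numeric",
                 thresholdPercent = "numeric", searchRadiusFactor = "numeric",
                 interpStep = "numeric"),
  prototype(thresholdPercent = 5, searchRadiusFactor = 3, interpStep = 0.1),
  validity = function(object) {
    if (object@dosePercent <= 0 || object@dtaMm <= 0)
      return("dose and DTA criteria must be positive")
    if (object@thresholdPercent < 0 || object@thresholdPercent >= 100)
      return("threshold must be in [0, 100)")
    TRUE
  })

#' Result of a 2D gamma comparison
#'
#' @slot gammaMap matrix of gamma values, `NaN` where the reference is below
#'   the low-dose threshold.
#' @slot passRate percent of evaluated points with gamma <= 1.
#' @slot meanGamma mean gamma over evaluated points.
#' @slot nEvaluated number of evaluated points.
#' @slot criteria the [GammaCriteria-class] used.
#' @exportClass GammaResult
setClass("GammaResult",
  representation(gammaMap = "matrix", passRate = "numeric",
                 meanGamma = "numeric", nEvaluated = "integer",
                 criteria = "GammaCriteria"),
  validity = function(object) {
    msg <- character()
    if (object@passRate < -1e-9 || object@passRate > 100 + 1e-9)
      msg <- c(msg, "passRate must be in [0, 100]")
    if (object@meanGamma < -1e-9) msg <- c(msg, "meanGamma must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' Per-field verification report of an end-to-end experiment
#'
#' @slot entries data.frame with one row per field and criteria set:
#'   `field`, `split`, `dosePercent`, `dtaMm`, `passRate`, `meanGamma`,
#'   `nEvaluated`.
#' @slot config the experiment configuration (list).
#' @slot seed integer master seed.
#' @exportClass VerificationReport
setClass("VerificationReport",
  representation(entries = "data.frame", config = "list", seed = "integer"))
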