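# Accessor generics and show methods. Slots are never reached into from user
# code; these accessors are the supported surface.

#' @rdname accessors
#' @param object an epidverify S4 object.
#' @export
setGeneric("beams", function(object) standardGeneric("beams"))
#' @rdname accessors
#' @export
setGeneric("controlPoints", function(object) standardGeneric("controlPoints"))
#' @rdname accessors
#' @export
setGeneric("monitorUnits", function(object) standardGeneric("monitorUnits"))
#' @rdname accessors
#' @export
setGeneric("gantryAngle", function(object) standardGeneric("gantryAngle"))
#' @rdname accessors
#' @export
setGeneric("originalGantryAngle", function(object) standardGeneric("originalGantryAngle"))
#' @rdname accessors
#' @export
setGeneric("voxels", function(object) standardGeneric("voxels"))
#' @rdname accessors
#' @export
setGeneric("gridSpacing", function(object) standardGeneric("gridSpacing"))
#' @rdname accessors
#' @export
setGeneric("gridOrigin", function(object) standardGeneric("gridOrigin"))
#' @rdname accessors
#' @export
setGeneric("isocentre", function(object) standardGeneric("isocentre"))
#' @rdname accessors
#' @export
setGeneric("imageValues", function(object) standardGeneric("imageValues"))
#' @rdname accessors
#' @export
setGeneric("pixelPitch", function(object) standardGeneric("pixelPitch"))
#' @rdname accessors
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))
#' @rdname accessors
#' @export
setGeneric("passRate", function(object) standardGeneric("passRate"))
#' @rdname accessors
#' @export
setGeneric("meanGamma", function(object) standardGeneric("meanGamma"))
#' @rdname accessors
#' @export
setGeneric("gammaMap", function(object) standardGeneric("gammaMap"))
#' @rdname accessors
#' @export
setGeneric("nEvaluated", function(object) standardGeneric("nEvaluated"))
#' @rdname accessors
#' @export
setGeneric("lossHistory", function(object) standardGeneric("lossHistory"))
#' @rdname accessors
#' @export
setGeneric("datasetSplit", function(object) standardGeneric("datasetSplit"))
#' @rdname accessors
#' @export
setGeneric("reportEntries", function(object) standardGeneric("reportEntries"))

#' Accessors for epidverify objects
#'
#' Small read-only accessors for the package's S4 classes.
#'
#' @name accessors
#' @aliases beams,TreatmentPlan-method
NULL

#' @rdname accessors
setMethod("beams", "TreatmentPlan", function(object) object@beams)
#' @rdname accessors
setMethod("controlPoints", "BeamField", function(object) object@controlPoints)
#' @rdname accessors
setMethod("monitorUnits", "BeamField", function(object) object@monitorUnits)
#' @rdname accessors
setMethod("monitorUnits", "TreatmentPlan", function(object)
  sum(vapply(object@beams, function(b) b@monitorUnits, numeric(1))))
#' @rdname accessors
setMethod("gantryAngle", "ControlPoint", function(object) object@gantry)
#' @rdname accessors
setMethod("gantryAngle", "BeamField", function(object)
  object@controlPoints[[1L]]@gantry)
#' @rdname accessors
setMethod("originalGantryAngle", "BeamField", function(object)
  object@originalGantryAngle)
#' @rdname accessors
setMethod("voxels", "CTVolume", function(object) object@voxels)
#' @rdname accessors
setMethod("voxels", "DoseVolume", function(object) object@values)
#' @rdname accessors
setMethod("gridSpacing", "CTVolume", function(object) object@spacing)
#' @rdname accessors
setMethod("gridSpacing", "DoseVolume", function(object) object@spacing)
#' @rdname accessors
setMethod("gridSpacing", "PlanarDose", function(object) object@spacing)
#' @rdname accessors
setMethod("gridOrigin", "CTVolume", function(object) object@origin)
#' @rdname accessors
setMethod("gridOrigin", "DoseVolume", function(object) object@origin)
#' @rdname accessors
setMethod("gridOrigin", "PlanarDose", function(object) object@origin)
#' @rdname accessors
setMethod("isocentre", "CTVolume", function(object) object@isocentre)
#' @rdname accessors
setMethod("isocentre", "DoseVolume", function(object) object@isocentre)
#' @rdname accessors
setMethod("imageValues", "PlanarDose", function(object) object@values)
#' @rdname accessors
setMethod("imageValues", "TransmissionImage", function(object) object@values)
#' @rdname accessors
setMethod("pixelPitch", "TransmissionImage", function(object) object@pixelPitch)
#' @rdname accessors
setMethod("provenance", "TransmissionImage", function(object) object@provenance)
#' @rdname accessors
setMethod("passRate", "GammaResult", function(object) object@passRate)
#' @rdname accessors
setMethod("meanGamma", "GammaResult", function(object) object@meanGamma)
#' @rdname accessors
setMethod("gammaMap", "GammaResult", function(object) object@gammaMap)
#' @rdname accessors
setMethod("nEvaluated", "GammaResult", function(object) object@nEvaluated)
#' @rdname accessors
setMethod("lossHistory", "TrainedModel", function(object) object@lossHistory)
#' @rdname accessors
setMethod("datasetSplit", "DatasetBundle", function(object)
  list(train = object@splitTrain, val = object@splitVal, test = object@splitTest))
#' @rdname accessors
setMethod("reportEntries", "VerificationReport", function(object) object@entries)

# -- show methods -----------------------------------------------------------

setMethod("show", "TreatmentPlan", function(object) {
  cat(sprintf("TreatmentPlan '%s' on %s: %d beam(s)\n",
              object@planId, object@machine, length(object@beams)))
  for (b in object@beams)
    cat(sprintf("  beam %-8s %6.1f MU, gantry %5.1f deg (original %5.1f), %d control points\n",
                b@beamId, b@monitorUnits, gantryAngle(b),
                b@originalGantryAngle, length(b@controlPoints)))
})

setMethod("show", "CTVolume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("CTVolume %d x %d x %d voxels, spacing %.2f x %.2f x %.2f mm, HU [%d, %d]\n",
              d[1], d[2], d[3], object@spacing[1], object@spacing[2],
              object@spacing[3], round(min(object@voxels)), round(max(object@voxels))))
})

setMethod("show", "CombinedCT", function(object) {
  callNextMethod()
  cat(sprintf("  combined CT: slab top %.0f cm below iso, %.0f cm thick (HU %d), gap HU %d, rotation %.1f deg\n",
              object@slabRecord$top_depth_cm, object@slabRecord$thickness_cm,
              object@slabRecord$hu, object@gapHU, object@rotationAppliedDeg))
})

setMethod("show", "TransmissionImage", function(object) {
  d <- dim(object@values)
  cat(sprintf("TransmissionImage %d x %d (%s), pitch %.4f mm, range [%.3g, %.3g]\n",
              d[1], d[2], object@provenance, object@pixelPitch[1],
              min(object@values), max(object@values)))
})

setMethod("show", "PlanarDose", function(object) {
  d <- dim(object@values)
  cat(sprintf("PlanarDose %d x %d at %.0f cm depth, pitch %.3f x %.3f mm, max %.3g\n",
              d[1], d[2], object@planeDepthCm, object@spacing[1],
              object@spacing[2], max(object@values)))
})

setMethod("show", "DatasetBundle", function(object) {
  cat(sprintf("DatasetBundle: %d pairs (train %d / val %d / test %d), seed %d\n",
              length(object@inputs), length(object@splitTrain),
              length(object@splitVal), length(object@splitTest), object@seed))
})

setMethod("show", "TrainedModel", function(object) {
  ns <- object@networkSpec; ts <- object@trainSpec
  n <- nrow(object@lossHistory)
  cat(sprintf("TrainedModel: U-net depth %d base %d on %d x %d; %d epoch(s), final train/val MSE %.3g / %.3g\n",
              ns@depth, ns@baseChannels, ns@height, ns@width, n,
              object@lossHistory$train[n], object@lossHistory$val[n]))
})

setMethod("show", "GammaResult", function(object) {
  cr <- object@criteria
  cat(sprintf("GammaResult %g%%/%g mm (%g%% threshold): pass rate %.2f%%, mean gamma %.3f over %d points\n",
              cr@dosePercent, cr@dtaMm, cr@thresholdPercent,
              object@passRate, object@meanGamma, object@nEvaluated))
})

setMethod("show", "GammaCriteria", function(object) {
  cat(sprintf("GammaCriteria: %g%%/%g mm, threshold %g%%, search radius %g x DTA, step DTA/%g\n",
              object@dosePercent, object@dtaMm, object@thresholdPercent,
              object@searchRadiusFactor, 1 / object@interpStep))
})

setMethod("show", "VerificationReport", function(object) {
  cat(sprintf("VerificationReport: %d entries, seed %d\n",
              nrow(object@entries), object@seed))
})
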