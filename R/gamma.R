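# 2D global gamma analysis between transmission images, plus the
# delivery-error sensitivity protocol.

#' Construct gamma criteria
#'
#' @param dosePercent dose-difference criterion, % of the reference-image
#'   maximum (global normalization).
#' @param dtaMm distance-to-agreement, mm.
#' @param thresholdPercent low-dose threshold, % of the reference maximum.
#' @param searchRadiusFactor search radius in multiples of `dtaMm`.
#' @param interpStep sub-pixel search step as a fraction of `dtaMm`.
#' @return A [GammaCriteria-class].
#' @export
gammaCriteria <- function(dosePercent, dtaMm, thresholdPercent = 5,
                          searchRadiusFactor = 3, interpStep = 0.1) {
  new("GammaCriteria", dosePercent = dosePercent, dtaMm = dtaMm,
      thresholdPercent = thresholdPercent,
      searchRadiusFactor = searchRadiusFactor, interpStep = interpStep)
}

.gamma_mats <- function(reference, evaluated) {
  ref <- if (is(reference, "TransmissionImage")) reference@values else reference
  ev <- if (is(evaluated, "TransmissionImage")) evaluated@values else evaluated
  if (!identical(dim(ref), dim(ev)))
    stop("reference and evaluated grids do not match: ",
         paste(dim(ref), collapse = "x"), " vs ", paste(dim(ev), collapse = "x"))
  pitch <- if (is(reference, "TransmissionImage")) reference@pixelPitch
           else c(1, 1)
  if (is(evaluated, "TransmissionImage") &&
      max(abs(pitch - evaluated@pixelPitch)) > 1e-9)
    stop("reference and evaluated pixel pitches differ")
  list(ref = ref, ev = ev, pitch = pitch)
}

#' Global 2D gamma index between a reference and an evaluated image
#'
#' For every reference point at or above the low-dose threshold, the gamma
#' value is the minimum over displacements `r` within the search radius of
#' `sqrt(|r|^2 / dta^2 + dD(r)^2 / (dd% x max(ref) / 100)^2)`, with the
#' evaluated image interpolated bilinearly on a sub-pixel grid. A point
#' passes when gamma <= 1.
#'
#' @param reference the reference [TransmissionImage-class] (or matrix; the
#'   global normalization and threshold come from its maximum).
#' @param evaluated the evaluated image on the same grid.
#' @param criteria a [GammaCriteria-class].
#' @param pitch pixel pitch in mm when matrices are passed.
#' @param exhaustive evaluate every displacement instead of the
#'   sorted-by-distance early-exit search (identical result, slower; used
#'   as the oracle in tests).
#' @param stepMm override of the interpolation step in mm.
#' @return A [GammaResult-class].
#' @export
gammaIndex <- function(reference, evaluated, criteria, pitch = NULL,
                       exhaustive = FALSE, stepMm = NULL) {
  stopifnot(is(criteria, "GammaCriteria"))
  m <- .gamma_mats(reference, evaluated)
  if (!is.null(pitch)) m$pitch <- rep_len(pitch, 2L)
  dmax <- max(m$ref)
  thr <- criteria@thresholdPercent / 100 * dmax
  if (dmax <= 0 || all(m$ref < thr))
    stop("nothing to evaluate: all reference points below threshold")
  step <- if (is.null(stepMm)) criteria@interpStep * criteria@dtaMm else stepMm
  g <- cpp_gamma(m$ref, m$ev, m$pitch[1], m$pitch[2],
                 criteria@dosePercent / 100 * dmax, criteria@dtaMm, thr,
                 criteria@searchRadiusFactor * criteria@dtaMm, step,
                 !exhaustive)
  ev <- g[!is.na(g)]
  new("GammaResult", gammaMap = g,
      passRate = 100 * mean(ev <= 1 + 1e-9),
      meanGamma = mean(ev), nEvaluated = length(ev), criteria = criteria)
}

#' Verify one field: predicted vs measured transmission image
#'
#' Runs the gamma comparison for each criteria set with the measured image
#' as reference and the predicted image as evaluated (the documented
#' convention; gamma is not exactly symmetric under swapping the roles).
#'
#' @param predicted,measured [TransmissionImage-class] objects on the
#'   analysis grid.
#' @param criteriaList list of [GammaCriteria-class] (default 3%/3 mm and
#'   2%/2 mm, 5% threshold).
#' @return named list of [GammaResult-class], keyed like `"3%/3mm"`.
#' @export
verifyField <- function(predicted, measured,
                        criteriaList = list(gammaCriteria(3, 3),
                                            gammaCriteria(2, 2))) {
  res <- lapply(criteriaList, function(cr)
    gammaIndex(measured, predicted, cr))
  names(res) <- vapply(criteriaList, function(cr)
    sprintf("%g%%/%gmm", cr@dosePercent, cr@dtaMm), character(1))
  res
}

#' Delivery-error sensitivity study
#'
#' Reproduces the sensitivity protocol on synthetic fields: for each of
#' `nFields` random multi-segment IMRT fields, the unperturbed predicted
#' transmission image is compared against the synthetic measured image of a
#' delivery containing each of the 21 protocol errors in turn, with global
#' gamma (3%/3 mm, 5% threshold by default). Dose, setup, gantry and MLC
#' errors (classes Ea-Ed) are delivered to the heterogeneous thorax-like
#' phantom; the phantom-size-change class (Ee) uses the 10 cm homogeneous
#' slab. The predictor is the true detector transform (training-free and
#' deterministic) unless a trained model is supplied.
#'
#' @param nFields number of fields (6 in the protocol).
#' @param model a [DetectorModel-class].
#' @param criteria a [GammaCriteria-class] (default 3%/3 mm, 5% threshold).
#' @param nx,ny analysis-grid size.
#' @param seed integer seed for the field sampling.
#' @param errors named list of [ErrorSpec-class]
#'   (default [sensitivityErrorSpecs()]).
#' @param predictor `"true-response"` or a [TrainedModel-class] used to
#'   predict from the unperturbed noisy dose.
#' @return data.frame of gamma pass rates: one row per error (plus the
#'   no-error control row), one column per field.
#' @export
sensitivityStudy <- function(nFields = 6L, model = detectorModel(),
                             criteria = gammaCriteria(3, 3), nx = 128L,
                             ny = 96L, seed = 1L,
                             errors = sensitivityErrorSpecs(),
                             predictor = "true-response") {
  set.seed(seed)
  beams <- lapply(seq_len(nFields), function(i)
    randomBeam(sprintf("S%d", i), nSegments = sample(3:8, 1)))
  thorax <- thoraxPhantom()
  slab10 <- slabPhantom(10)
  dg <- epidGrid(nx + 16L, ny + 16L, 400 / nx)
  predict_ti <- function(beam, phantom) {
    clean <- waterDose(beam, phantom, model, grid = dg, noise = FALSE)
    if (is(predictor, "TrainedModel")) {
      predictTI(predictor, cropResample(clean, nx = nx, ny = ny))
    } else trueResponse(clean, model, nx = nx, ny = ny)
  }
  measure_ti <- function(beam, phantom, error) {
    pert <- waterDose(beam, phantom, model, error = error, grid = dg,
                      noise = FALSE)
    ti <- trueResponse(pert, model, nx = nx, ny = ny)
    ti@provenance <- "synthetic"
    ti
  }
  rows <- c("No error", names(errors))
  out <- matrix(NA_real_, length(rows), nFields,
                dimnames = list(rows, vapply(beams, function(b) b@beamId,
                                             character(1))))
  for (f in seq_len(nFields)) {
    pred_thorax <- predict_ti(beams[[f]], thorax)
    pred_slab <- predict_ti(beams[[f]], slab10)
    meas0 <- measure_ti(beams[[f]], thorax, NULL)
    out["No error", f] <- passRate(gammaIndex(meas0, pred_thorax, criteria))
    for (lbl in names(errors)) {
      slab_class <- errors[[lbl]]@kind == "slab_add"
      pred <- if (slab_class) pred_slab else pred_thorax
      meas <- measure_ti(beams[[f]], if (slab_class) slab10 else thorax,
                         errors[[lbl]])
      out[lbl, f] <- passRate(gammaIndex(meas, pred, criteria))
    }
  }
  as.data.frame(out)
}
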