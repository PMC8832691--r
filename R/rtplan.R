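# RT plan model: constructors, DICOM RT Plan read/write, zero-gantry plan
# splitting, and MLC aperture rasterisation.

.RTPLAN_SOP_CLASS <- "1.2.840.10008.5.1.4.1.1.481.5"
.CT_SOP_CLASS <- "1.2.840.10008.5.1.4.1.1.2"

#' Construct a control point
#'
#' @param index integer control-point index (0-based).
#' @param weight cumulative meterset weight in `[0, 1]`.
#' @param mlcA,mlcB numeric(60) leaf-edge positions in mm at the isocentre
#'   plane (IEC crossline; bank B on the negative side, so `mlcB <= mlcA`).
#' @param jawX,jawY numeric(2) jaw positions in mm.
#' @param gantry gantry angle in degrees.
#' @return A [ControlPoint-class].
#' @export
controlPoint <- function(index, weight, mlcA, mlcB,
                         jawX = c(-200, 200), jawY = c(-200, 200), gantry = 0) {
  new("ControlPoint", index = as.integer(index), weight = as.numeric(weight),
      mlcA = as.numeric(mlcA), mlcB = as.numeric(mlcB),
      jawX = as.numeric(jawX), jawY = as.numeric(jawY),
      gantry = as.numeric(gantry) %% 360)
}

#' Construct a beam field
#'
#' @param beamId character id, unique within the plan.
#' @param monitorUnits MU > 0.
#' @param controlPoints list of [ControlPoint-class], ordered, cumulative
#'   meterset weight from 0 to 1.
#' @param originalGantryAngle gantry angle of the source plan (defaults to
#'   the control points' common gantry angle).
#' @return A [BeamField-class].
#' @export
beamField <- function(beamId, monitorUnits, controlPoints,
                      originalGantryAngle = NULL) {
  if (is.null(originalGantryAngle))
    originalGantryAngle <- controlPoints[[1L]]@gantry
  new("BeamField", beamId = as.character(beamId),
      monitorUnits = as.numeric(monitorUnits), controlPoints = controlPoints,
      originalGantryAngle = as.numeric(originalGantryAngle))
}

#' Construct a treatment plan
#'
#' @param planId character plan label.
#' @param beams list of [BeamField-class].
#' @param machine treatment machine name.
#' @return A [TreatmentPlan-class].
#' @export
treatmentPlan <- function(planId, beams, machine = "Trilogy") {
  new("TreatmentPlan", planId = as.character(planId), machine = machine,
      beams = beams)
}

#' Millennium-120 leaf-pair boundaries
#'
#' Inline (leaf-travel-orthogonal) boundaries of the 60 leaf pairs in mm at
#' the isocentre plane: 10 outer pairs of 10 mm, 40 central pairs of 5 mm,
#' 10 outer pairs of 10 mm, spanning -200 to +200 mm.
#'
#' @return numeric(61) boundary positions in mm.
#' @export
mlcLeafBoundaries <- function() {
  widths <- c(rep(10, 10), rep(5, 40), rep(10, 10))
  c(-200, -200 + cumsum(widths))
}

# ---------------------------------------------------------------------------
# DICOM RT Plan I/O
# ---------------------------------------------------------------------------

#' Write a treatment plan as a DICOM RT Plan file
#'
#' Explicit-VR little-endian RT Plan with beam, control-point, MLC/jaw and
#' fraction-group (beam meterset) content. This is the writer used for the
#' single-field zero-gantry plans produced by [splitPlan()].
#'
#' @param plan a [TreatmentPlan-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeRTPlan <- function(plan, path) {
  stopifnot(is(plan, "TreatmentPlan"))
  beam_items <- lapply(seq_along(plan@beams), function(bi) {
    b <- plan@beams[[bi]]
    cp_items <- lapply(b@controlPoints, function(cp) {
      bld <- list(
        c(.d_str_elem(0x300A, 0x00B8, "CS", "ASYMX"), .d_ds(0x300A, 0x011C, cp@jawX)),
        c(.d_str_elem(0x300A, 0x00B8, "CS", "ASYMY"), .d_ds(0x300A, 0x011C, cp@jawY)),
        c(.d_str_elem(0x300A, 0x00B8, "CS", "MLCX"),
          .d_ds(0x300A, 0x011C, c(cp@mlcB, cp@mlcA))))
      c(.d_is(0x300A, 0x0112, cp@index),
        .d_ds(0x300A, 0x011E, cp@gantry),
        .d_ds(0x300A, 0x0134, cp@weight),
        .d_sq(0x300A, 0x011A, bld))
    })
    c(.d_is(0x300A, 0x00C0, bi),
      .d_str_elem(0x300A, 0x00C2, "LO", b@beamId),
      .d_str_elem(0x300A, 0x00B2, "SH", plan@machine),
      .d_is(0x300A, 0x00D0, 0),                       # number of wedges
      .d_ds(0x300A, 0x010E, 1),                       # final cumulative weight
      .d_is(0x300A, 0x0110, length(b@controlPoints)),
      .d_sq(0x300A, 0x0111, cp_items))
  })
  ref_items <- lapply(seq_along(plan@beams), function(bi)
    c(.d_is(0x300C, 0x0006, bi), .d_ds(0x300A, 0x0086, plan@beams[[bi]]@monitorUnits)))
  fg_item <- c(.d_is(0x300A, 0x0071, 1), .d_is(0x300A, 0x0078, 1),
               .d_sq(0x300C, 0x0004, ref_items))
  uid <- .d_new_uid()
  ds <- c(
    .d_str_elem(0x0008, 0x0016, "UI", .RTPLAN_SOP_CLASS),
    .d_str_elem(0x0008, 0x0018, "UI", uid),
    .d_str_elem(0x0008, 0x0060, "CS", "RTPLAN"),
    .d_str_elem(0x300A, 0x0002, "SH", plan@planId),
    .d_sq(0x300A, 0x00B0, beam_items),
    .d_sq(0x300A, 0x0070, list(fg_item)))
  writeBin(.d_file(.RTPLAN_SOP_CLASS, uid, ds), path)
  invisible(path)
}

#' Read a DICOM RT Plan
#'
#' Supports static-gantry IMRT plans with MLCX leaf sequences. Plans with
#' wedges, a missing MLC sequence, or a gantry angle that varies within a
#' beam are rejected as unsupported.
#'
#' @param path path to an RT Plan file (explicit VR little endian).
#' @return A [TreatmentPlan-class] with leaf positions in mm at the
#'   isocentre plane and `originalGantryAngle` set from the plan.
#' @export
readRTPlan <- function(path) {
  els <- .d_parse_file(path)
  sop <- .d_el_str(els, 0x0008, 0x0016)
  if (!is.null(sop) && sop != .RTPLAN_SOP_CLASS)
    stop("not an RT Plan (SOP class ", sop, ")")
  beam_items <- .d_el_items(els, 0x300A, 0x00B0)
  if (is.null(beam_items) || !length(beam_items)) stop("plan contains no beams")
  # MU per referenced beam number from the fraction group
  mu <- list()
  fg <- .d_el_items(els, 0x300A, 0x0070)
  if (!is.null(fg))
    for (g in fg)
      for (rb in .d_el_items(g, 0x300C, 0x0004) %||% list()) {
        n <- .d_el_num(rb, 0x300C, 0x0006)
        mu[[as.character(n)]] <- .d_el_num(rb, 0x300A, 0x0086)
      }
  beams <- lapply(beam_items, function(b) {
    bn <- .d_el_num(b, 0x300A, 0x00C0)
    nm <- .d_el_str(b, 0x300A, 0x00C2) %||% as.character(bn)
    nw <- .d_el_num(b, 0x300A, 0x00D0)
    if (!is.null(nw) && nw > 0)
      stop("unsupported plan: beam ", nm, " uses wedges")
    cps_items <- .d_el_items(b, 0x300A, 0x0111)
    if (is.null(cps_items)) stop("unsupported plan: beam ", nm, " has no control points")
    gantry <- NA_real_; jx <- NULL; jy <- NULL
    cps <- lapply(cps_items, function(it) {
      g <- .d_el_num(it, 0x300A, 0x011E)
      if (!is.null(g)) gantry <<- g
      mlcA <- NULL; mlcB <- NULL
      for (bd in .d_el_items(it, 0x300A, 0x011A) %||% list()) {
        typ <- .d_el_str(bd, 0x300A, 0x00B8)
        pos <- .d_el_num(bd, 0x300A, 0x011C)
        if (typ %in% c("X", "ASYMX")) jx <<- pos
        else if (typ %in% c("Y", "ASYMY")) jy <<- pos
        else if (typ %in% c("MLCX")) { mlcB <- pos[1:60]; mlcA <- pos[61:120] }
      }
      list(index = .d_el_num(it, 0x300A, 0x0112),
           weight = .d_el_num(it, 0x300A, 0x0134),
           gantry = gantry, mlcA = mlcA, mlcB = mlcB,
           jawX = jx, jawY = jy)
    })
    if (any(vapply(cps, function(cp) is.null(cp$mlcA), logical(1))))
      stop("unsupported plan: beam ", nm, " lacks an MLCX sequence on some control points")
    g_all <- vapply(cps, function(cp) cp$gantry, numeric(1))
    if (diff(range(g_all)) > 1e-6)
      stop("unsupported plan: gantry angle varies within beam ", nm, " (static-gantry IMRT only)")
    cps <- lapply(cps, function(cp)
      controlPoint(cp$index, cp$weight, cp$mlcA, cp$mlcB,
                   cp$jawX %||% c(-200, 200), cp$jawY %||% c(-200, 200),
                   cp$gantry))
    m <- mu[[as.character(bn)]]
    if (is.null(m)) stop("no beam meterset found for beam ", nm)
    beamField(nm, m, cps)
  })
  treatmentPlan(.d_el_str(els, 0x300A, 0x0002) %||% "plan", beams,
                machine = .d_el_str(beam_items[[1]], 0x300A, 0x00B2) %||% "unknown")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---------------------------------------------------------------------------
# Plan splitting
# ---------------------------------------------------------------------------

#' Split a plan into single-field zero-gantry plans
#'
#' Each beam of the input becomes its own one-beam plan whose control-point
#' gantry angles are all set to zero; the source gantry angle is preserved
#' in `originalGantryAngle` (it later drives the combined-CT counter
#' rotation). Per-beam MU and control-point weights are copied verbatim.
#' Splitting a single-beam zero-gantry plan is a fixed point.
#'
#' @param plan a [TreatmentPlan-class].
#' @return list of single-beam [TreatmentPlan-class] objects, one per beam.
#' @export
splitPlan <- function(plan) {
  stopifnot(is(plan, "TreatmentPlan"))
  if (!length(plan@beams)) stop("cannot split an empty plan")
  lapply(seq_along(plan@beams), function(i) {
    b <- plan@beams[[i]]
    cps <- lapply(b@controlPoints, function(cp) {
      cp@gantry <- 0; cp
    })
    b2 <- beamField(b@beamId, b@monitorUnits, cps,
                    originalGantryAngle = b@originalGantryAngle)
    treatmentPlan(sprintf("%s_%s", plan@planId, b@beamId), list(b2),
                  machine = plan@machine)
  })
}

# ---------------------------------------------------------------------------
# Aperture rasterisation
# ---------------------------------------------------------------------------

#' Regular grid at the isocentre plane
#'
#' @param nx,ny number of cells (crossline, inline).
#' @param pitch cell size in mm (<= 1 mm recommended for area accuracy).
#' @return list with cell-centre coordinate vectors `x`, `y` (mm) and `pitch`.
#' @export
isoGrid <- function(nx, ny, pitch = 1) {
  list(x = (seq_len(nx) - (nx + 1) / 2) * pitch,
       y = (seq_len(ny) - (ny + 1) / 2) * pitch,
       pitch = pitch)
}

#' Binary aperture mask of a control point
#'
#' A cell is open (1) iff its centre lies strictly between the bank-B and
#' bank-A edges of the leaf pair covering its inline coordinate and inside
#' the jaws. Points outside the 400 mm leaf-bank span are blocked.
#'
#' @param cp a [ControlPoint-class].
#' @param grid a grid spec from [isoGrid()].
#' @return integer matrix `length(grid$x)` x `length(grid$y)`.
#' @export
apertureMask <- function(cp, grid) {
  stopifnot(is(cp, "ControlPoint"))
  bounds <- mlcLeafBoundaries()
  pair <- findInterval(grid$y, bounds, rightmost.closed = TRUE)
  pair[grid$y < bounds[1] | grid$y > bounds[61]] <- NA_integer_
  mask <- matrix(0L, length(grid$x), length(grid$y))
  xin_jaw <- grid$x > cp@jawX[1] & grid$x < cp@jawX[2]
  for (j in seq_along(grid$y)) {
    p <- pair[j]
    if (is.na(p) || grid$y[j] <= cp@jawY[1] || grid$y[j] >= cp@jawY[2]) next
    open <- xin_jaw & grid$x > cp@mlcB[p] & grid$x < cp@mlcA[p]
    mask[open, j] <- 1L
  }
  mask
}

# ---------------------------------------------------------------------------
# Synthetic plan fixtures
# ---------------------------------------------------------------------------

#' Random multi-segment IMRT field
#'
#' Samples a static-gantry beam with `nSegments + 1` control points whose
#' apertures are random rectangles (up to `maxFieldMm` square) with optional
#' per-leaf jitter ("stepped" apertures), a random aperture drift between
#' consecutive control points, and random meterset increments.
#'
#' @param beamId beam id.
#' @param nSegments number of delivered segments (>= 1).
#' @param gantry gantry angle in degrees.
#' @param maxFieldMm maximum aperture side at the isocentre plane, mm.
#' @param stepSdMm per-leaf edge jitter SD, mm (0 for pure rectangles).
#' @param muRange range the beam MU is drawn from.
#' @return A [BeamField-class]. Uses the current RNG stream.
#' @export
randomBeam <- function(beamId = "B1", nSegments = 5L, gantry = 0,
                       maxFieldMm = 200, stepSdMm = 3, muRange = c(60, 300)) {
  ncp <- nSegments + 1L
  w <- c(0, cumsum(stats::runif(nSegments, 0.3, 1)))
  w <- w / w[ncp]
  cx <- stats::runif(1, -30, 30); cy <- stats::runif(1, -30, 30)
  hw <- stats::runif(1, 20, maxFieldMm / 2); hh <- stats::runif(1, 20, maxFieldMm / 2)
  bounds <- mlcLeafBoundaries()
  centres <- (bounds[-61] + bounds[-1]) / 2
  cps <- vector("list", ncp)
  for (k in seq_len(ncp)) {
    dx <- stats::runif(1, -15, 15); dy <- stats::runif(1, -10, 10)
    a <- rep(-200, 60); b <- rep(-200, 60)   # parked: closed at -200
    inrow <- centres > cy + dy - hh & centres < cy + dy + hh
    gapL <- cx + dx - hw + stats::rnorm(60, 0, stepSdMm)
    gapR <- cx + dx + hw + stats::rnorm(60, 0, stepSdMm)
    gapR <- pmax(gapR, gapL)  # keep B <= A
    b[inrow] <- pmax(gapL[inrow], -195)
    a[inrow] <- pmin(pmax(gapR[inrow], b[inrow]), 195)
    cps[[k]] <- controlPoint(k - 1L, w[k], a, b,
                             jawX = c(min(b[inrow], -10) - 5, max(a[inrow], 10) + 5),
                             jawY = c(cy + dy - hh - 5, cy + dy + hh + 5),
                             gantry = gantry)
  }
  beamField(beamId, stats::runif(1, muRange[1], muRange[2]), cps)
}

#' Random multi-beam treatment plan fixture
#'
#' @param nBeams number of beams.
#' @param segmentRange range of segment counts per beam.
#' @param gantryAngles gantry angles recycled over beams (degrees).
#' @param seed optional integer seed for reproducibility.
#' @param ... passed to [randomBeam()].
#' @return A [TreatmentPlan-class].
#' @export
randomPlan <- function(nBeams = 3L, segmentRange = c(2L, 10L),
                       gantryAngles = c(0, 30, 120, 270), seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  gA <- rep_len(gantryAngles, nBeams)
  beams <- lapply(seq_len(nBeams), function(i)
    randomBeam(beamId = sprintf("B%d", i),
               nSegments = sample(seq(segmentRange[1], segmentRange[2]), 1),
               gantry = gA[i], ...))
  treatmentPlan(sprintf("synth%04d", sample.int(9999L, 1)), beams)
}
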