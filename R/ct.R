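# Combined-CT construction: couch HU substitution, anti-clockwise axial
# rotation by the gantry angle, axial extension, and insertion of the
# equivalent-EPID solid-water slab with its air gap.

#' Construct a CT volume
#'
#' @param voxels 3D HU array indexed `[x, y, z]` (crossline, beam axis at
#'   gantry 0 with +y = depth below isocentre, inline).
#' @param spacing numeric(3) voxel spacing, mm.
#' @param origin numeric(3) patient-coordinate position of the centre of
#'   voxel `[1, 1, 1]`, mm.
#' @param isocentre numeric(3) isocentre position, mm.
#' @return A [CTVolume-class].
#' @export
ctVolume <- function(voxels, spacing, origin = NULL, isocentre = c(0, 0, 0)) {
  if (is.null(origin)) {
    d <- dim(voxels)
    origin <- isocentre - (d - 1) / 2 * spacing  # centred on the isocentre
  }
  new("CTVolume", voxels = voxels, spacing = as.numeric(spacing),
      origin = as.numeric(origin), isocentre = as.numeric(isocentre))
}

.ct_coords <- function(ct) {
  d <- dim(ct@voxels)
  list(x = ct@origin[1] + (seq_len(d[1]) - 1) * ct@spacing[1],
       y = ct@origin[2] + (seq_len(d[2]) - 1) * ct@spacing[2],
       z = ct@origin[3] + (seq_len(d[3]) - 1) * ct@spacing[3])
}

#' HU at a patient-coordinate point (nearest voxel)
#'
#' @param ct a [CTVolume-class].
#' @param point numeric(3) position in mm.
#' @return the HU of the nearest voxel.
#' @export
huAt <- function(ct, point) {
  idx <- round((point - ct@origin) / ct@spacing) + 1
  d <- dim(ct@voxels)
  if (any(idx < 1) || any(idx > d)) stop("point outside the CT volume")
  ct@voxels[idx[1], idx[2], idx[3]]
}

#' Replace couch voxels by a fixed HU
#'
#' Substitutes the TPS-recommended couch HU into the voxels flagged by
#' `couchMask`; all other voxels are untouched.
#'
#' @param ct a [CTVolume-class].
#' @param couchMask logical/0-1 array congruent with the CT grid.
#' @param hu replacement HU.
#' @return The modified [CTVolume-class].
#' @export
replaceCouch <- function(ct, couchMask, hu) {
  stopifnot(is(ct, "CTVolume"))
  if (!identical(dim(couchMask), dim(ct@voxels)))
    stop("couch mask shape does not match the CT grid")
  ct@voxels[as.logical(couchMask)] <- hu
  ct
}

#' Rotate every axial slice anti-clockwise about the isocentre axis
#'
#' "Anti-clockwise" is interpreted in the standard axial display (patient
#' left on image right, anterior up): a feature on the image right moves to
#' the image top. The emulated delivery sets the gantry to zero and counter
#' rotates the CT instead. Bilinear interpolation, out-of-support voxels
#' filled with -1000 HU, grid shape preserved.
#'
#' @param ct a [CTVolume-class].
#' @param angleDeg rotation angle in degrees (wrapped mod 360).
#' @return The rotated [CTVolume-class].
#' @export
rotateAxial <- function(ct, angleDeg) {
  stopifnot(is(ct, "CTVolume"))
  angleDeg <- angleDeg %% 360
  if (angleDeg == 0) return(ct)
  th <- angleDeg * pi / 180
  co <- cos(th); si <- sin(th)
  crd <- .ct_coords(ct)
  xr <- crd$x - ct@isocentre[1]; yr <- crd$y - ct@isocentre[2]
  # inverse map of the anti-clockwise display rotation (see vignette)
  Xin <- outer(xr, yr, function(x, y) co * x - si * y) + ct@isocentre[1]
  Yin <- outer(xr, yr, function(x, y) si * x + co * y) + ct@isocentre[2]
  d <- dim(ct@voxels)
  vox <- ct@voxels
  for (k in seq_len(d[3]))
    vox[, , k] <- cpp_bilinear_map(ct@voxels[, , k],
                                   crd$x[1], ct@spacing[1],
                                   crd$y[1], ct@spacing[2],
                                   Xin, Yin, -1000)
  ct@voxels <- pmin(pmax(vox, -1024), 3071)
  ct
}

#' Extend the CT grid to cover the equivalent-EPID geometry
#'
#' Pads the volume with air (-1000 HU) so the beam-axis extent reaches at
#' least `minDepthBelowIsoCm` below the isocentre and the crossline extent
#' covers `lateralHalfWidthCm` on both sides. Original voxels and the
#' physical position of every retained voxel are unchanged.
#'
#' @param ct a [CTVolume-class].
#' @param minDepthBelowIsoCm minimum depth below the isocentre, cm (>= 52 so
#'   the slab bottom fits; default 60).
#' @param lateralHalfWidthCm crossline half extent, cm (default 26).
#' @return The padded [CTVolume-class].
#' @export
extendAxial <- function(ct, minDepthBelowIsoCm = 60, lateralHalfWidthCm = 26) {
  stopifnot(is(ct, "CTVolume"))
  if (minDepthBelowIsoCm < 52)
    stop("minDepthBelowIsoCm must be >= 52 cm to contain the slab bottom")
  d <- dim(ct@voxels); sp <- ct@spacing
  crd <- .ct_coords(ct)
  need_y <- ct@isocentre[2] + minDepthBelowIsoCm * 10
  pad_y <- max(0L, ceiling((need_y - crd$y[d[2]]) / sp[2]))
  need_xlo <- ct@isocentre[1] - lateralHalfWidthCm * 10
  need_xhi <- ct@isocentre[1] + lateralHalfWidthCm * 10
  pad_xlo <- max(0L, ceiling((crd$x[1] - need_xlo) / sp[1]))
  pad_xhi <- max(0L, ceiling((need_xhi - crd$x[d[1]]) / sp[1]))
  if (pad_y == 0 && pad_xlo == 0 && pad_xhi == 0) return(ct)
  nd <- c(d[1] + pad_xlo + pad_xhi, d[2] + pad_y, d[3])
  vox <- array(-1000, nd)
  vox[pad_xlo + seq_len(d[1]), seq_len(d[2]), ] <- ct@voxels
  ct@voxels <- vox
  ct@origin[1] <- ct@origin[1] - pad_xlo * sp[1]
  ct
}

#' Insert the equivalent-EPID solid-water slab
#'
#' Assigns HU 0 to a 5 cm slab whose top face lies 47 cm below the
#' isocentre along the beam axis (so the scoring plane 50 cm below the
#' isocentre sits 3 cm deep, behind its build-up), and -1000 HU to the air
#' gap between `airFromMm` and the slab top. Slab/gap assignment happens
#' after any rotation, so these regions are exact, with no interpolation
#' bleed.
#'
#' @param ct a [CTVolume-class] whose extent reaches >= 52 cm below the
#'   isocentre (see [extendAxial()]).
#' @param slabLateralMm numeric(2) slab extent (crossline, inline), mm.
#' @param airFromMm depth (mm below the isocentre) from which air is
#'   explicitly assigned down to the slab top; `NULL` assigns none beyond
#'   the padding already present.
#' @param topDepthCm,thicknessCm slab geometry, cm.
#' @return A [CombinedCT-class].
#' @export
insertSolidWater <- function(ct, slabLateralMm = c(500, 400), airFromMm = NULL,
                             topDepthCm = 47, thicknessCm = 5) {
  stopifnot(is(ct, "CTVolume"))
  crd <- .ct_coords(ct)
  depth <- crd$y - ct@isocentre[2]
  top <- topDepthCm * 10; bot <- top + thicknessCm * 10
  if (max(depth) < bot - ct@spacing[2] / 2)
    stop("CT extent does not reach ", bot / 10,
         " cm below the isocentre; run extendAxial() first")
  in_slab_y <- depth >= top - 1e-9 & depth < bot - 1e-9
  in_x <- abs(crd$x - ct@isocentre[1]) <= slabLateralMm[1] / 2
  in_z <- abs(crd$z - ct@isocentre[3]) <= slabLateralMm[2] / 2
  vox <- ct@voxels
  if (!is.null(airFromMm)) {
    gap_y <- depth >= airFromMm & depth < top - 1e-9
    vox[, gap_y, ] <- -1000
  }
  vox[in_x, in_slab_y, in_z] <- 0
  rot <- if (is(ct, "CombinedCT")) ct@rotationAppliedDeg else 0
  new("CombinedCT", voxels = vox, spacing = ct@spacing, origin = ct@origin,
      isocentre = ct@isocentre,
      slabRecord = list(top_depth_cm = topDepthCm, thickness_cm = thicknessCm,
                        hu = 0L, lateral_mm = slabLateralMm),
      gapHU = -1000, rotationAppliedDeg = rot)
}

#' Build the combined CT for one zero-gantry beam
#'
#' Runs the full pre-processing chain: couch HU substitution (skipped with a
#' warning when no couch mask is supplied), anti-clockwise axial rotation by
#' the beam's original gantry angle, axial extension, and solid-water slab
#' insertion. The applied rotation is recorded on the result.
#'
#' @param ct the plan [CTVolume-class].
#' @param beam a [BeamField-class] carrying `originalGantryAngle` (e.g. from
#'   [splitPlan()]).
#' @param couchMask optional logical array flagging couch voxels.
#' @param config list of overrides: `couch_hu` (default -300),
#'   `min_depth_cm` (60), `lateral_half_cm` (26), `slab_lateral_mm`
#'   (c(500, 400)), `air_from_mm` (NULL).
#' @return A [CombinedCT-class] with `rotationAppliedDeg` set.
#' @export
buildCombinedCT <- function(ct, beam, couchMask = NULL, config = list()) {
  stopifnot(is(ct, "CTVolume"), is(beam, "BeamField"))
  cfg <- utils::modifyList(
    list(couch_hu = -300, min_depth_cm = 60, lateral_half_cm = 26,
         slab_lateral_mm = c(500, 400), air_from_mm = NULL), config)
  if (is.null(couchMask)) {
    warning("no couch mask supplied; couch HU substitution skipped")
  } else {
    ct <- replaceCouch(ct, couchMask, cfg$couch_hu)
  }
  ang <- beam@originalGantryAngle
  ct <- rotateAxial(ct, ang)
  ct <- extendAxial(ct, cfg$min_depth_cm, cfg$lateral_half_cm)
  cc <- insertSolidWater(ct, slabLateralMm = cfg$slab_lateral_mm,
                         airFromMm = cfg$air_from_mm)
  cc@rotationAppliedDeg <- ang %% 360
  cc
}

# ---------------------------------------------------------------------------
# DICOM CT series I/O
# ---------------------------------------------------------------------------

#' Write a CT volume as a DICOM CT series
#'
#' One explicit-VR little-endian file per axial slice with 16-bit signed
#' pixel data (rescale slope 1, intercept 0).
#'
#' @param ct a [CTVolume-class] (or [CombinedCT-class]).
#' @param dir output directory (created if needed).
#' @return character vector of file paths, invisibly.
#' @export
writeCTSeries <- function(ct, dir) {
  stopifnot(is(ct, "CTVolume"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(ct@voxels)
  series_uid <- .d_new_uid()
  crd <- .ct_coords(ct)
  paths <- character(d[3])
  for (k in seq_len(d[3])) {
    hu <- as.integer(round(ct@voxels[, , k]))
    pix <- writeBin(hu, raw(), size = 2, endian = "little")
    uid <- paste0(series_uid, ".", k)
    ds <- c(
      .d_str_elem(0x0008, 0x0016, "UI", .CT_SOP_CLASS),
      .d_str_elem(0x0008, 0x0018, "UI", uid),
      .d_str_elem(0x0008, 0x0060, "CS", "CT"),
      .d_str_elem(0x0020, 0x000E, "UI", series_uid),
      .d_is(0x0020, 0x0013, k),
      .d_ds(0x0020, 0x0032, c(ct@origin[1], ct@origin[2], crd$z[k])),
      .d_ds(0x0020, 0x0037, c(1, 0, 0, 0, 1, 0)),
      .d_elem(0x0028, 0x0002, "US", .d_u16(1)),
      .d_str_elem(0x0028, 0x0004, "CS", "MONOCHROME2"),
      .d_elem(0x0028, 0x0010, "US", .d_u16(d[2])),   # rows = y
      .d_elem(0x0028, 0x0011, "US", .d_u16(d[1])),   # cols = x
      .d_ds(0x0028, 0x0030, c(ct@spacing[2], ct@spacing[1])),
      .d_elem(0x0028, 0x0100, "US", .d_u16(16)),
      .d_elem(0x0028, 0x0101, "US", .d_u16(16)),
      .d_elem(0x0028, 0x0102, "US", .d_u16(15)),
      .d_elem(0x0028, 0x0103, "US", .d_u16(1)),
      .d_ds(0x0028, 0x1052, 0),
      .d_ds(0x0028, 0x1053, 1),
      .d_elem(0x7FE0, 0x0010, "OW", pix))
    paths[k] <- file.path(dir, sprintf("ct%04d.dcm", k))
    writeBin(.d_file(.CT_SOP_CLASS, uid, ds), paths[k])
  }
  invisible(paths)
}

#' Read a DICOM CT series from a directory
#'
#' @param dir directory of `.dcm` slices (explicit VR little endian,
#'   axis-aligned axial orientation).
#' @param isocentre numeric(3) isocentre in patient coordinates, mm.
#' @return A [CTVolume-class]; slices are sorted by their z position.
#' @export
readCTSeries <- function(dir, isocentre = c(0, 0, 0)) {
  files <- list.files(dir, pattern = "\\.dcm$", full.names = TRUE)
  if (!length(files)) stop("no .dcm files in ", dir)
  slices <- lapply(files, function(f) {
    els <- .d_parse_file(f)
    ipp <- .d_el_num(els, 0x0020, 0x0032)
    nrow_ <- .d_read_u16(.d_el(els, 0x0028, 0x0010)$bytes, 1L)
    ncol_ <- .d_read_u16(.d_el(els, 0x0028, 0x0011)$bytes, 1L)
    ps <- .d_el_num(els, 0x0028, 0x0030)
    slope <- .d_el_num(els, 0x0028, 0x1053) %||% 1
    icpt <- .d_el_num(els, 0x0028, 0x1052) %||% 0
    pix <- readBin(.d_el(els, 0x7FE0, 0x0010)$bytes, "integer",
                   n = nrow_ * ncol_, size = 2, endian = "little", signed = TRUE)
    list(z = ipp[3], x0 = ipp[1], y0 = ipp[2], dx = ps[2], dy = ps[1],
         hu = matrix(pix * slope + icpt, ncol_, nrow_))  # [x, y]
  })
  slices <- slices[order(vapply(slices, function(s) s$z, numeric(1)))]
  s1 <- slices[[1]]
  vox <- array(0, c(nrow(s1$hu), ncol(s1$hu), length(slices)))
  for (k in seq_along(slices)) vox[, , k] <- slices[[k]]$hu
  dz <- if (length(slices) > 1) slices[[2]]$z - s1$z else 1
  ctVolume(vox, spacing = c(s1$dx, s1$dy, dz),
           origin = c(s1$x0, s1$y0, s1$z), isocentre = isocentre)
}

#' Smooth synthetic phantom CT for tests and examples
#'
#' An elliptical water-equivalent body with a smooth HU gradient on an air
#' background; deliberately asymmetric left-right so rotations are
#' observable.
#'
#' @param n voxels per axis (cube).
#' @param spacing voxel spacing, mm.
#' @return A [CTVolume-class] centred on the isocentre.
#' @export
syntheticPhantomCT <- function(n = 48L, spacing = 4) {
  ax <- (seq_len(n) - (n + 1) / 2) * spacing
  vox <- array(-1000, c(n, n, n))
  rx <- 0.7 * max(ax); ry <- 0.5 * max(ax)
  for (k in seq_len(n)) {
    R2 <- outer(ax / rx, ax / ry, function(x, y) x^2 + y^2)
    body <- R2 <= 1
    sl <- matrix(-1000, n, n)
    sl[body] <- (40 * outer(ax / max(ax), rep(1, n))[body] +  # left-right gradient
                 20 * (1 - R2[body]))
    vox[, , k] <- sl
  }
  ctVolume(vox, spacing = rep(spacing, 3))
}
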