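# Equivalent-EPID plane handling: coronal plane extraction from a dose
# volume, physical-window crop/resampling to the analysis grid, and
# measured-image import.

#' Construct a dose volume
#'
#' @param values 3D dose array indexed `[x, y, z]` (same axes as
#'   [CTVolume-class]).
#' @param spacing,origin,isocentre grid geometry in mm.
#' @return A [DoseVolume-class].
#' @export
doseVolume <- function(values, spacing, origin = NULL, isocentre = c(0, 0, 0)) {
  if (is.null(origin)) {
    d <- dim(values)
    origin <- isocentre - (d - 1) / 2 * spacing
  }
  new("DoseVolume", values = values, spacing = as.numeric(spacing),
      origin = as.numeric(origin), isocentre = as.numeric(isocentre))
}

#' Construct a planar dose map
#'
#' @param values 2D matrix `[crossline, inline]`.
#' @param spacing numeric(2) pixel pitch, mm.
#' @param origin numeric(2) offset of the grid centre from the beam axis, mm.
#' @param planeDepthCm depth below the isocentre, cm.
#' @return A [PlanarDose-class].
#' @export
planarDose <- function(values, spacing, origin = c(0, 0), planeDepthCm = 50) {
  new("PlanarDose", values = values, spacing = as.numeric(spacing),
      origin = as.numeric(origin), planeDepthCm = as.numeric(planeDepthCm))
}

#' Construct a transmission image
#'
#' @param values 2D matrix on the 4:3 analysis grid (`[crossline, inline]`).
#' @param provenance `"measured"`, `"predicted"` or `"synthetic"`.
#' @return A [TransmissionImage-class]; the pixel pitch follows from the
#'   shape (400 mm / ncol crossline).
#' @export
transmissionImage <- function(values, provenance = "synthetic") {
  pitch <- c(400 / nrow(values), 300 / ncol(values))
  new("TransmissionImage", values = values, pixelPitch = pitch,
      provenance = provenance)
}

# pixel-centre coordinates of the analysis grid (mm from the beam axis)
.ti_coords <- function(nx, ny, widthMm = 400, heightMm = 300) {
  list(x = (seq_len(nx) - (nx + 1) / 2) * widthMm / nx,
       y = (seq_len(ny) - (ny + 1) / 2) * heightMm / ny)
}

#' Extract the coronal dose plane at the equivalent-EPID depth
#'
#' Returns the plane `depthCm` below the isocentre along the beam axis,
#' either the nearest stored plane or a linear interpolation between the
#' two bracketing planes.
#'
#' @param vol a [DoseVolume-class].
#' @param depthCm plane depth below the isocentre, cm (default 50).
#' @param method `"linear"` (default) or `"nearest"`.
#' @return A [PlanarDose-class] (`values[x, z]`, crossline by inline).
#' @export
extractPlane <- function(vol, depthCm = 50, method = c("linear", "nearest")) {
  stopifnot(is(vol, "DoseVolume"))
  method <- match.arg(method)
  d <- dim(vol@values)
  y <- vol@origin[2] + (seq_len(d[2]) - 1) * vol@spacing[2]
  target <- vol@isocentre[2] + depthCm * 10
  if (target < min(y) - 1e-9 || target > max(y) + 1e-9)
    stop("plane ", depthCm, " cm below the isocentre lies outside the dose volume")
  f <- (target - y[1]) / vol@spacing[2]
  j0 <- floor(f); a <- f - j0
  if (method == "nearest" || a < 1e-9 || j0 + 2 > d[2]) {
    plane <- vol@values[, round(f) + 1, ]
  } else {
    plane <- (1 - a) * vol@values[, j0 + 1, ] + a * vol@values[, j0 + 2, ]
  }
  ctr_x <- vol@origin[1] + (d[1] - 1) / 2 * vol@spacing[1] - vol@isocentre[1]
  ctr_z <- vol@origin[3] + (d[3] - 1) / 2 * vol@spacing[3] - vol@isocentre[3]
  planarDose(plane, spacing = vol@spacing[c(1, 3)], origin = c(ctr_x, ctr_z),
             planeDepthCm = depthCm)
}

#' Crop and resample a dose plane to the analysis grid
#'
#' Lays the target pixel centres on a physical window (40 cm x 30 cm by
#' default) centred on the beam axis and samples the source grid
#' bilinearly. The window is defined in mm, not integer source pixels, so
#' non-integer source pitches (e.g. the 50 cm / 512 ~ 0.977 mm Monte-Carlo
#' export pitch) are handled exactly.
#'
#' @param plane a [PlanarDose-class] covering the window.
#' @param nx,ny target grid size (must keep the 4:3 aspect).
#' @param widthMm,heightMm physical window, mm.
#' @param provenance provenance tag of the result.
#' @return A [TransmissionImage-class]-shaped grid holding resampled dose.
#' @export
cropResample <- function(plane, nx = 256L, ny = 192L,
                         widthMm = 400, heightMm = 300,
                         provenance = "synthetic") {
  stopifnot(is(plane, "PlanarDose"))
  d <- dim(plane@values)
  src_x <- plane@origin[1] + (seq_len(d[1]) - (d[1] + 1) / 2) * plane@spacing[1]
  src_y <- plane@origin[2] + (seq_len(d[2]) - (d[2] + 1) / 2) * plane@spacing[2]
  tc <- .ti_coords(nx, ny, widthMm, heightMm)
  if (min(tc$x) < src_x[1] - 1e-9 || max(tc$x) > src_x[d[1]] + 1e-9 ||
      min(tc$y) < src_y[1] - 1e-9 || max(tc$y) > src_y[d[2]] + 1e-9)
    stop("source plane does not cover the ", widthMm / 10, " x ",
         heightMm / 10, " cm analysis window")
  out <- cpp_bilinear_grid(plane@values, src_x[1], plane@spacing[1],
                           src_y[1], plane@spacing[2], tc$x, tc$y, 0)
  transmissionImage(out, provenance = provenance)
}

#' Load a measured EPID transmission image
#'
#' Accepts a 1024 x 768 greyscale matrix (or a 16-bit PNG/TIFF file path)
#' covering the 40 cm x 30 cm panel and downsamples by exact 4 x 4 block
#' averaging to the 256 x 192 analysis grid. Block averaging (rather than
#' point sampling) matches the detector's signal integration and the exact
#' 4:1 pixel ratio.
#'
#' @param image numeric matrix `[1024, 768]` (crossline, inline), or a file
#'   path. Matrices with dims `[768, 1024]` (row-major image readers) are
#'   transposed automatically.
#' @param maxValue full-scale value used when reading normalised image
#'   files (16-bit: 65535).
#' @return A [TransmissionImage-class] with provenance `"measured"`.
#' @export
loadMeasuredTI <- function(image, maxValue = 65535) {
  if (is.character(image)) {
    ext <- tolower(tools::file_ext(image))
    img <- switch(ext,
      png = png::readPNG(image) * maxValue,
      tif = ,
      tiff = tiff::readTIFF(image) * maxValue,
      stop("unsupported image format: ", ext))
    if (length(dim(img)) == 3L) img <- img[, , 1]
    image <- t(img)[, rev(seq_len(nrow(img)))]  # row-major top-down -> [x, y]
  }
  if (all(dim(image) == c(768L, 1024L))) image <- t(image)
  if (!all(dim(image) == c(1024L, 768L)))
    stop("measured TI must be 1024 x 768, got ", paste(dim(image), collapse = " x "))
  transmissionImage(cpp_block_mean(image, 4L, 4L), provenance = "measured")
}

#' Normalize an image to its maximum
#'
#' @param x a matrix, [PlanarDose-class] or [TransmissionImage-class].
#' @return the same type with values divided by their maximum.
#' @export
normalizeMax <- function(x) {
  if (is(x, "PlanarDose")) { x@values <- x@values / max(x@values); return(x) }
  if (is(x, "TransmissionImage")) { x@values <- x@values / max(x@values); return(x) }
  x / max(x)
}
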