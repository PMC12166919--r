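#' Read one channel of an RGB TIFF scan
#'
#' Reads a flatbed-scanner TIFF and returns the requested color channel as a
#' [ScanImage-class] with pixel values on the 16-bit scale. 8-bit files are
#' accepted and promoted by a factor 257. The resolution is taken from the
#' file's resolution tags when present (inch units); otherwise the
#' \code{dpi} fallback argument is used.
#'
#' @param path path to an RGB TIFF file.
#' @param channel \code{"red"} (default), \code{"green"} or \code{"blue"}.
#' @param role scan role recorded in the result.
#' @param dpi fallback resolution when the file carries no resolution tag.
#' @return A [ScanImage-class].
#' @seealso [saveScan()], [reduceScanStack()]
#' @export
loadScan <- function(path, channel = "red", role = "unexposed", dpi = 127) {
  if (!file.exists(path))
    .stopf("formatError", "scan file not found: %s", path)
  arr <- tryCatch(tiff::readTIFF(path, info = TRUE),
                  error = function(e)
                    .stopf("formatError", "not a readable TIFF (%s): %s",
                           conditionMessage(e), path))
  ci <- match(channel, c("red", "green", "blue"))
  if (is.na(ci)) .stopf("formatError", "unknown channel '%s'", channel)
  if (length(dim(arr)) < 3L || dim(arr)[3] < ci)
    .stopf("formatError", "channel '%s' not present in %s", channel, path)
  bits <- attr(arr, "bits.per.sample")
  plane <- arr[, , ci]
  # readTIFF returns values on [0, 1]; restore the stored integer scale,
  # promoting 8-bit to the 16-bit scale (x 257)
  pv <- if (!is.null(bits) && bits == 8L) round(plane * 255) * 257
        else round(plane * 65535)
  xres <- attr(arr, "x.resolution")
  unit <- attr(arr, "resolution.unit")
  fdpi <- if (!is.null(xres) && is.finite(xres) && xres > 0 &&
              (is.null(unit) || unit == "inch")) xres else dpi
  ScanImage(pv, dpi = fdpi, channel = channel, role = role)
}

#' Write a ScanImage as a 16-bit RGB TIFF
#'
#' The single channel raster is replicated into all three planes (the red
#' plane carries the signal for densitometry); pixel values are rounded to
#' the nearest 16-bit integer. Round-trips through [loadScan()] are
#' bit-exact for integer rasters.
#'
#' @param image a [ScanImage-class].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
saveScan <- function(image, path) {
  pv <- pmin(pmax(.rhaz(pixels(image)), 0), 65535)
  arr <- array(pv / 65535, dim = c(nrow(pv), ncol(pv), 3L))
  tiff::writeTIFF(arr, path, bits.per.sample = 16L, compression = "none",
                  reduce = FALSE)
  invisible(path)
}

#' Reduce a stack of repeat scans to one clean raster
#'
#' The scan-reduction chain: each repeat scan is 3 x 3 median filtered
#' (impulse noise removal), the filtered scans are averaged pixel-wise in
#' floating point, and the average is passed through an adaptive Wiener
#' filter with a 7 x 7 window. Both filters use reflect padding.
#'
#' @param scans list of [ScanImage-class] objects with identical shape, dpi,
#'   channel and role.
#' @param medianWindow median-filter window; only the default 3 is
#'   implemented (the smallest impulse-removing window).
#' @param wienerWindow Wiener window size (odd), default 7.
#' @param applyWiener logical; skip the final Wiener step when FALSE. The
#'   median-filtered average (pre-Wiener) raster is where ROI pixel spreads
#'   are measured for uncertainty propagation: the adaptive Wiener filter
#'   removes exactly the within-window variation that an ROI sd measures,
#'   so spreads taken after it would understate the ROI-mean error.
#' @return A [ScanImage-class] of the same shape.
#' @examples
#' sc <- ScanImage(matrix(30000, 16, 16))
#' out <- reduceScanStack(list(sc, sc, sc))
#' stopifnot(max(abs(pixels(out) - 30000)) < 1e-9)
#' @export
reduceScanStack <- function(scans, medianWindow = 3L, wienerWindow = 7L,
                            applyWiener = TRUE) {
  if (length(scans) < 1L) .stopf("dimensionError", "empty scan stack")
  if (medianWindow != 3L)
    .stopf("parameterError", "only a 3x3 median window is supported")
  d <- dim(pixels(scans[[1]]))
  for (s in scans) {
    if (!identical(dim(pixels(s)), d))
      .stopf("dimensionError", "scan stack has mismatched raster shapes")
    if (dpi(s) != dpi(scans[[1]]) || scanChannel(s) != scanChannel(scans[[1]]) ||
        scanRole(s) != scanRole(scans[[1]]))
      .stopf("dimensionError", "scan stack mixes dpi, channel or role")
  }
  filt <- lapply(scans, function(s) .medianFilter3(pixels(s)))
  avg <- Reduce(`+`, filt) / length(filt)
  out <- if (applyWiener) .wienerFilter(avg, as.integer(wienerWindow)) else avg
  out <- pmin(pmax(out, 0), 65535)
  ScanImage(out, dpi = dpi(scans[[1]]), channel = scanChannel(scans[[1]]),
            role = scanRole(scans[[1]]))
}

#' Mean pixel value over a millimetre ROI
#'
#' Converts the mm-specified region to whole pixels (round half away from
#' zero, minimum 1 x 1, centered on the nearest pixel center) and returns
#' the mean and sample standard deviation of the covered pixel values. At
#' 127 dpi a 1 x 1 mm ROI covers exactly 5 x 5 pixels.
#'
#' @param image a [ScanImage-class].
#' @param centerMm numeric length-2 (x, y) center in mm, raster-corner
#'   origin.
#' @param roiMm numeric length-2 (width, height) in mm; default 1 x 1 mm.
#' @return A [RoiStat-class].
#' @export
roiMean <- function(image, centerMm, roiMm = c(1, 1)) {
  p <- pixels(image)
  sc <- dpi(image) / MM_PER_INCH
  cx <- .rhaz(centerMm[1] * sc) + 1L  # 1-based column of nearest pixel center
  cy <- .rhaz(centerMm[2] * sc) + 1L
  wx <- max(1L, .rhaz(roiMm[1] * sc))
  wy <- max(1L, .rhaz(roiMm[2] * sc))
  x1 <- cx - (wx - 1L) %/% 2L; x2 <- x1 + wx - 1L
  y1 <- cy - (wy - 1L) %/% 2L; y2 <- y1 + wy - 1L
  if (x1 < 1L || y1 < 1L || x2 > ncol(p) || y2 > nrow(p))
    .stopf("boundsError", "ROI [%d..%d, %d..%d] outside raster %d x %d",
           y1, y2, x1, x2, nrow(p), ncol(p))
  v <- as.vector(p[y1:y2, x1:x2])
  new("RoiStat", meanPV = mean(v),
      sdPV = if (length(v) > 1L) stats::sd(v) else 0,
      nPx = length(v))
}

#' ROI at the raster center
#'
#' Convenience wrapper around [roiMean()] with the ROI centered on the
#' geometric center of the raster, where a uniform-field calibration strip
#' carries its nominal dose.
#'
#' @inheritParams roiMean
#' @return A [RoiStat-class].
#' @export
centerRoiMean <- function(image, roiMm = c(1, 1)) {
  p <- pixels(image)
  cmm <- c((ncol(p) - 1) / 2, (nrow(p) - 1) / 2) * MM_PER_INCH / dpi(image)
  roiMean(image, cmm, roiMm)
}
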