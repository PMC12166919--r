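# Shared small helpers. The package-wide spatial convention is
# position_mm = index * 25.4 / dpi, 0-based index, origin at the raster
# corner.

MM_PER_INCH <- 25.4

# round half away from zero (deterministic, dpi-exact at 127 dpi)
.rhaz <- function(x) sign(x) * floor(abs(x) + 0.5)

.mmToPx <- function(mm, dpi) mm * dpi / MM_PER_INCH

.pxPositionsMm <- function(n, dpi) (seq_len(n) - 1) * MM_PER_INCH / dpi

#' Positions (mm) of raster columns and rows
#'
#' @param image a [ScanImage-class] or [NetODMap-class].
#' @return list with \code{x_mm} (columns) and \code{y_mm} (rows), 0-based
#'   pixel convention.
#' @export
pixelPositionsMm <- function(image) {
  p <- if (is(image, "ScanImage")) pixels(image) else netOD(image)
  list(x_mm = .pxPositionsMm(ncol(p), dpi(image)),
       y_mm = .pxPositionsMm(nrow(p), dpi(image)))
}

# stop() with a classed condition so callers/tests can distinguish failures
.stopf <- function(class, fmt, ...) {
  stop(structure(class = c(class, "wedgecalError", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}

#' Export a profile to CSV
#'
#' Writes columns \code{position_mm}, \code{netod}, \code{sigma_netod}.
#'
#' @param profile a [NetODProfile-class].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeProfileCSV <- function(profile, path) {
  utils::write.csv(data.frame(position_mm = positions(profile),
                              netod = netOD(profile),
                              sigma_netod = netODSigma(profile)),
                   path, row.names = FALSE)
  invisible(path)
}

#' Export a reduced raster to CSV
#'
#' Long format with header \code{x_mm}, \code{y_mm}, \code{pv}.
#'
#' @param image a [ScanImage-class].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeImageCSV <- function(image, path) {
  p <- pixels(image)
  pos <- pixelPositionsMm(image)
  df <- data.frame(x_mm = rep(pos$x_mm, each = nrow(p)),
                   y_mm = rep(pos$y_mm, times = ncol(p)),
                   pv = as.vector(p))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export calibration points to CSV
#'
#' @param points data frame with \code{netod}, \code{sigma_netod},
#'   \code{dose_gy}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writePointsCSV <- function(points, path) {
  utils::write.csv(points[, c("netod", "sigma_netod", "dose_gy")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Serialize / restore a calibration curve as JSON
#'
#' Schema: \code{{a, b, n, sigma_a, sigma_b, netod_domain, fit_meta}}.
#'
#' @param curve a [CalibrationCurve-class].
#' @param path output (input) file path.
#' @return \code{writeCalibrationJSON}: the path, invisibly;
#'   \code{readCalibrationJSON}: a [CalibrationCurve-class].
#' @export
writeCalibrationJSON <- function(curve, path) {
  jsonlite::write_json(
    list(a = coefA(curve), b = coefB(curve), n = coefN(curve),
         sigma_a = sigmaA(curve), sigma_b = sigmaB(curve),
         netod_domain = netODDomain(curve), fit_meta = curve@fit_meta),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeCalibrationJSON
#' @export
readCalibrationJSON <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  CalibrationCurve(a = j$a, b = j$b, n = j$n, sigma_a = j$sigma_a,
                   sigma_b = j$sigma_b, netod_domain = as.numeric(j$netod_domain),
                   fit_meta = as.list(j$fit_meta))
}
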