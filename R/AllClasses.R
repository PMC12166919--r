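#' ScanImage: a single-channel flatbed-scanner raster
#'
#' Holds one color channel of a digitized film strip as a numeric matrix of
#' pixel values (PV) on the 16-bit scale, together with the scan resolution
#' and the role the scan plays in densitometry (unexposed, exposed or
#' zero-light background). Pixel values are kept in floating point so that
#' reduced (filtered/averaged) rasters lose no precision; rasters are rounded
#' to integers only when written to disk.
#'
#' The package-wide spatial convention is \code{position_mm = index * 25.4 /
#' dpi} with 0-based indices and the origin at the raster corner; matrix rows
#' run along the scanner y axis and columns along x.
#'
#' @slot pixels numeric matrix of pixel values in [0, 65535].
#' @slot dpi scan resolution in dots per inch.
#' @slot channel one of \code{"red"}, \code{"green"}, \code{"blue"}.
#' @slot role one of \code{"unexposed"}, \code{"exposed"}, \code{"background"}.
#' @export
setClass("ScanImage",
  representation(pixels = "matrix", dpi = "numeric",
                 channel = "character", role = "character"),
  prototype(dpi = 127, channel = "red", role = "unexposed"))

setValidity("ScanImage", function(object) {
  p <- object@pixels
  if (!is.numeric(p)) return("pixels must be a numeric matrix")
  if (nrow(p) < 2L || ncol(p) < 2L) return("raster must be at least 2 x 2")
  if (anyNA(p) || any(p < 0) || any(p > 65535))
    return("pixel values must lie in [0, 65535]")
  if (length(object@dpi) != 1L || !is.finite(object@dpi) || object@dpi <= 0)
    return("dpi must be a single positive number")
  if (!object@channel %in% c("red", "green", "blue"))
    return("channel must be one of red, green, blue")
  if (!object@role %in% c("unexposed", "exposed", "background"))
    return("role must be one of unexposed, exposed, background")
  TRUE
})

#' Construct a ScanImage
#'
#' @param pixels numeric matrix of pixel values in [0, 65535].
#' @param dpi scan resolution (dots per inch).
#' @param channel color channel the raster came from.
#' @param role scan role: \code{"unexposed"}, \code{"exposed"} or
#'   \code{"background"}.
#' @return A [ScanImage-class] object.
#' @examples
#' img <- ScanImage(matrix(30000, 10, 10), dpi = 127, role = "unexposed")
#' dpi(img)
#' @export
ScanImage <- function(pixels, dpi = 127, channel = "red", role = "unexposed") {
  new("ScanImage", pixels = pixels, dpi = dpi, channel = channel, role = role)
}

#' @rdname accessors
#' @export
setMethod("pixels", "ScanImage", function(object) object@pixels)
#' @rdname accessors
#' @export
setMethod("dpi", "ScanImage", function(object) object@dpi)
#' @rdname accessors
#' @export
setMethod("scanChannel", "ScanImage", function(object) object@channel)
#' @rdname accessors
#' @export
setMethod("scanRole", "ScanImage", function(object) object@role)

setMethod("show", "ScanImage", function(object) {
  cat(sprintf("ScanImage: %d x %d px, %g dpi, channel=%s, role=%s\n",
              nrow(object@pixels), ncol(object@pixels), object@dpi,
              object@channel, object@role))
  cat(sprintf("  PV range [%.1f, %.1f]\n",
              min(object@pixels), max(object@pixels)))
})

#' RoiStat: summary statistics of a rectangular region of interest
#'
#' @slot meanPV mean pixel value over the ROI.
#' @slot sdPV sample standard deviation of the pixel values within the ROI
#'   (the conservative spread convention: the ROI sd itself, not the standard
#'   error of the mean).
#' @slot nPx number of pixels covered.
#' @export
setClass("RoiStat",
  representation(meanPV = "numeric", sdPV = "numeric", nPx = "integer"))

setValidity("RoiStat", function(object) {
  if (object@nPx < 1L) return("nPx must be >= 1")
  if (!is.finite(object@sdPV) || object@sdPV < 0) return("sdPV must be >= 0")
  TRUE
})

setMethod("show", "RoiStat", function(object) {
  cat(sprintf("RoiStat: mean PV %.2f, sd %.3f over %d px\n",
              object@meanPV, object@sdPV, object@nPx))
})

#' NetODMap: per-pixel net optical density with uncertainty
#'
#' Element-wise net optical density of an exposed film relative to its
#' unexposed state, background corrected, with a per-pixel one-sigma
#' uncertainty from local (1 mm neighborhood) pixel-value spread. Pixels at
#' which the log argument is non-positive (saturated film, bad background)
#' are masked rather than fatal.
#'
#' @slot netod numeric matrix of netOD values (NA where masked).
#' @slot sigma numeric matrix of one-sigma netOD uncertainties.
#' @slot mask logical matrix, TRUE where the pixel is invalid.
#' @slot dpi scan resolution in dots per inch.
#' @export
setClass("NetODMap",
  representation(netod = "matrix", sigma = "matrix", mask = "matrix",
                 dpi = "numeric"))

setValidity("NetODMap", function(object) {
  d <- dim(object@netod)
  if (!identical(d, dim(object@sigma)) || !identical(d, dim(object@mask)))
    return("netod, sigma and mask must share dimensions")
  if (!is.logical(object@mask)) return("mask must be logical")
  if (any(object@sigma < 0, na.rm = TRUE)) return("sigma must be >= 0")
  if (object@dpi <= 0) return("dpi must be positive")
  TRUE
})

#' Construct a NetODMap
#'
#' Mostly used internally by [netODMap()]; exported so that profile-level
#' operations can be exercised on directly constructed maps.
#'
#' @param netod numeric matrix of netOD values.
#' @param sigma numeric matrix of netOD uncertainties (default all zero).
#' @param dpi resolution in dots per inch.
#' @param mask logical matrix of invalid pixels (default: NA entries of
#'   \code{netod}).
#' @return A [NetODMap-class].
#' @export
NetODMap <- function(netod, sigma = NULL, dpi = 127, mask = NULL) {
  if (is.null(sigma)) sigma <- array(0, dim(netod))
  if (is.null(mask)) mask <- is.na(netod)
  new("NetODMap", netod = netod, sigma = sigma, mask = mask, dpi = dpi)
}

#' @rdname accessors
#' @export
setMethod("netOD", "NetODMap", function(object) object@netod)
#' @rdname accessors
#' @export
setMethod("netODSigma", "NetODMap", function(object) object@sigma)
#' @rdname accessors
#' @export
setMethod("dpi", "NetODMap", function(object) object@dpi)

setMethod("show", "NetODMap", function(object) {
  cat(sprintf("NetODMap: %d x %d px, %g dpi, %d masked px\n",
              nrow(object@netod), ncol(object@netod), object@dpi,
              sum(object@mask)))
})

#' NetODProfile: a 1-D netOD profile along the wedge gradient axis
#'
#' Positions are in millimetres; once a field has been segmented they are
#' CAX-centered (origin at the midpoint of the detected field edges).
#' Uncertainties are one-sigma per position. The \code{meta} list records
#' provenance: detected edges, whether the profile was mirrored so that
#' netOD decreases with increasing position, the nominal CAX dose of the
#' exposure, and the field-length sanity check outcome.
#'
#' @slot positions_mm strictly increasing positions (mm).
#' @slot netod netOD value per position.
#' @slot sigma one-sigma uncertainty per position.
#' @slot meta list of provenance fields.
#' @export
setClass("NetODProfile",
  representation(positions_mm = "numeric", netod = "numeric",
                 sigma = "numeric", meta = "list"),
  prototype(meta = list()))

setValidity("NetODProfile", function(object) {
  n <- length(object@positions_mm)
  if (length(object@netod) != n || length(object@sigma) != n)
    return("positions, netod and sigma must have equal length")
  if (n > 1L && any(diff(object@positions_mm) <= 0))
    return("positions must be strictly increasing")
  if (any(object@sigma < 0, na.rm = TRUE)) return("sigma must be >= 0")
  TRUE
})

#' Construct a NetODProfile
#'
#' @param positions_mm strictly increasing positions (mm).
#' @param netod netOD values, same length.
#' @param sigma one-sigma uncertainties (default zero).
#' @param meta optional provenance list.
#' @return A [NetODProfile-class].
#' @export
NetODProfile <- function(positions_mm, netod, sigma = NULL, meta = list()) {
  if (is.null(sigma)) sigma <- numeric(length(netod))
  new("NetODProfile", positions_mm = positions_mm, netod = netod,
      sigma = sigma, meta = meta)
}

#' @rdname accessors
#' @export
setMethod("positions", "NetODProfile", function(object) object@positions_mm)
#' @rdname accessors
#' @export
setMethod("netOD", "NetODProfile", function(object) object@netod)
#' @rdname accessors
#' @export
setMethod("netODSigma", "NetODProfile", function(object) object@sigma)
#' @rdname accessors
#' @export
setMethod("profileMeta", "NetODProfile", function(object) object@meta)

setMethod("show", "NetODProfile", function(object) {
  n <- length(object@positions_mm)
  cat(sprintf("NetODProfile: %d samples, x in [%.2f, %.2f] mm, netOD in [%.4f, %.4f]\n",
              n, min(object@positions_mm), max(object@positions_mm),
              min(object@netod), max(object@netod)))
})

#' @describeIn NetODProfile-class number of samples in the profile.
#' @param x a \code{NetODProfile}.
#' @export
setMethod("length", "NetODProfile", function(x) length(x@positions_mm))

#' WedgeReference: the measured reference wedge dose profile
#'
#' Normalized lateral dose profile of the physical wedge at the measurement
#' plane, with dose 1 at the central axis (CAX), plus the wedge transmission
#' at the CAX and the beam geometry. Under the self-similarity assumption,
#' the dose profile of a wedge exposure delivering \code{D_CAX} is this
#' profile multiplied by \code{D_CAX}.
#'
#' @slot positions_mm CAX-centered positions along the gradient axis (mm),
#'   strictly increasing.
#' @slot dose_rel relative dose (1 at CAX), strictly positive.
#' @slot attenuation_cax wedge transmission at CAX, in (0, 1).
#' @slot geometry list with \code{fieldSizeCm}, \code{ssdCm}, \code{depthCm},
#'   \code{wedgeAngleDeg}.
#' @export
setClass("WedgeReference",
  representation(positions_mm = "numeric", dose_rel = "numeric",
                 attenuation_cax = "numeric", geometry = "list"))

setValidity("WedgeReference", function(object) {
  x <- object@positions_mm; y <- object@dose_rel
  if (length(x) != length(y)) return("positions and dose_rel lengths differ")
  if (length(x) < 2L) return("reference needs at least two samples")
  if (any(diff(x) <= 0)) return("positions must be strictly increasing")
  if (any(y <= 0)) return("dose_rel must be positive everywhere")
  if (min(x) > 0 || max(x) < 0) return("reference must bracket the CAX (x = 0)")
  at0 <- stats::approx(x, y, xout = 0)$y
  if (abs(at0 - 1) > 1e-6) return("dose_rel at CAX must equal 1 within 1e-6")
  ac <- object@attenuation_cax
  if (length(ac) != 1L || ac <= 0 || ac >= 1)
    return("attenuation_cax must lie in (0, 1)")
  need <- c("fieldSizeCm", "ssdCm", "depthCm")
  if (!all(need %in% names(object@geometry)))
    return("geometry must contain fieldSizeCm, ssdCm, depthCm")
  TRUE
})

#' Construct a WedgeReference
#'
#' @param positions_mm CAX-centered positions (mm), strictly increasing.
#' @param dose_rel relative dose profile, 1 at CAX.
#' @param attenuation_cax CAX transmission of the wedge, in (0, 1).
#' @param geometry list with \code{fieldSizeCm}, \code{ssdCm}, \code{depthCm}
#'   and optionally \code{wedgeAngleDeg}.
#' @return A [WedgeReference-class].
#' @export
WedgeReference <- function(positions_mm, dose_rel, attenuation_cax, geometry) {
  new("WedgeReference", positions_mm = positions_mm, dose_rel = dose_rel,
      attenuation_cax = attenuation_cax, geometry = geometry)
}

#' @rdname accessors
#' @export
setMethod("positions", "WedgeReference", function(object) object@positions_mm)
#' @rdname accessors
#' @export
setMethod("doseRel", "WedgeReference", function(object) object@dose_rel)
#' @rdname accessors
#' @export
setMethod("attenuationCAX", "WedgeReference",
          function(object) object@attenuation_cax)
#' @rdname accessors
#' @export
setMethod("geometry", "WedgeReference", function(object) object@geometry)

setMethod("show", "WedgeReference", function(object) {
  g <- object@geometry
  cat(sprintf(
    "WedgeReference: %d samples, x in [%.1f, %.1f] mm, CAX transmission %.4f\n",
    length(object@positions_mm), min(object@positions_mm),
    max(object@positions_mm), object@attenuation_cax))
  cat(sprintf("  geometry: %g x %g cm field, SSD %g cm, depth %g cm\n",
              g$fieldSizeCm, g$fieldSizeCm, g$ssdCm, g$depthCm))
})

#' WedgeExposure: the scan set of one wedge-field film strip
#'
#' @slot scans list with elements \code{unexposed}, \code{exposed},
#'   \code{background}, each a list of [ScanImage-class] repeat scans.
#' @slot d_cax_gy nominal absorbed dose at the CAX (Gy), positive.
#' @slot axis wedge gradient axis in the raster: \code{"x"} (along columns)
#'   or \code{"y"} (along rows).
#' @export
setClass("WedgeExposure",
  representation(scans = "list", d_cax_gy = "numeric", axis = "character"),
  prototype(axis = "x"))

setValidity("WedgeExposure", function(object) {
  if (!all(c("unexposed", "exposed", "background") %in% names(object@scans)))
    return("scans must contain unexposed, exposed and background stacks")
  if (length(object@d_cax_gy) != 1L || object@d_cax_gy <= 0)
    return("d_cax_gy must be a single positive number")
  if (!object@axis %in% c("x", "y")) return("axis must be 'x' or 'y'")
  TRUE
})

#' Construct a WedgeExposure
#'
#' @param scans list with \code{unexposed}, \code{exposed}, \code{background}
#'   stacks of [ScanImage-class] objects.
#' @param d_cax_gy nominal CAX dose (Gy).
#' @param axis wedge gradient axis, \code{"x"} or \code{"y"}.
#' @return A [WedgeExposure-class].
#' @export
WedgeExposure <- function(scans, d_cax_gy, axis = "x") {
  new("WedgeExposure", scans = scans, d_cax_gy = d_cax_gy, axis = axis)
}

setMethod("show", "WedgeExposure", function(object) {
  cat(sprintf("WedgeExposure: D_CAX = %g Gy, axis %s, %d/%d/%d repeat scans\n",
              object@d_cax_gy, object@axis,
              length(object@scans$unexposed), length(object@scans$exposed),
              length(object@scans$background)))
})

#' CalibrationCurve: fitted dose response D = a netOD + b netOD^n
#'
#' The two-term power-law film response with the exponent held fixed during
#' fitting. Parameter uncertainties come from the covariance of the
#' least-squares fit; \code{netod_domain} records the netOD range actually
#' covered by the calibration points, so that later evaluations can flag
#' extrapolation.
#'
#' @slot a linear coefficient (Gy).
#' @slot b power-term coefficient (Gy).
#' @slot n fixed exponent (dimensionless, > 1).
#' @slot sigma_a one-sigma uncertainty of \code{a} (Gy).
#' @slot sigma_b one-sigma uncertainty of \code{b} (Gy).
#' @slot netod_domain length-2 numeric, netOD range of the fit.
#' @slot fit_meta list of fit diagnostics (iterations, residual sd, weighting,
#'   number of points).
#' @export
setClass("CalibrationCurve",
  representation(a = "numeric", b = "numeric", n = "numeric",
                 sigma_a = "numeric", sigma_b = "numeric",
                 netod_domain = "numeric", fit_meta = "list"),
  prototype(fit_meta = list()))

setValidity("CalibrationCurve", function(object) {
  if (object@n <= 1) return("exponent n must be > 1")
  if (object@sigma_a < 0 || object@sigma_b < 0)
    return("parameter uncertainties must be >= 0")
  d <- object@netod_domain
  if (length(d) != 2L || !(d[1] < d[2]))
    return("netod_domain must be (min, max) with min < max")
  TRUE
})

#' Construct a CalibrationCurve
#'
#' @param a,b fitted coefficients (Gy).
#' @param n fixed exponent (> 1).
#' @param sigma_a,sigma_b one-sigma parameter uncertainties (Gy).
#' @param netod_domain length-2 netOD range covered by the fit.
#' @param fit_meta optional diagnostics list.
#' @return A [CalibrationCurve-class].
#' @examples
#' cc <- CalibrationCurve(a = 10, b = 40, netod_domain = c(0.05, 0.5))
#' doseFromNetOD(cc, 0.3)
#' @export
CalibrationCurve <- function(a, b, n = 2.5, sigma_a = 0, sigma_b = 0,
                             netod_domain, fit_meta = list()) {
  new("CalibrationCurve", a = a, b = b, n = n, sigma_a = sigma_a,
      sigma_b = sigma_b, netod_domain = netod_domain, fit_meta = fit_meta)
}

#' @rdname accessors
#' @export
setMethod("coefA", "CalibrationCurve", function(object) object@a)
#' @rdname accessors
#' @export
setMethod("coefB", "CalibrationCurve", function(object) object@b)
#' @rdname accessors
#' @export
setMethod("coefN", "CalibrationCurve", function(object) object@n)
#' @rdname accessors
#' @export
setMethod("sigmaA", "CalibrationCurve", function(object) object@sigma_a)
#' @rdname accessors
#' @export
setMethod("sigmaB", "CalibrationCurve", function(object) object@sigma_b)
#' @rdname accessors
#' @export
setMethod("netODDomain", "CalibrationCurve",
          function(object) object@netod_domain)

setMethod("show", "CalibrationCurve", function(object) {
  cat(sprintf("CalibrationCurve: D = a netOD + b netOD^%g\n", object@n))
  cat(sprintf("  a = %.4f +/- %.4f Gy,  b = %.4f +/- %.4f Gy\n",
              object@a, object@sigma_a, object@b, object@sigma_b))
  cat(sprintf("  netOD domain [%.4f, %.4f]\n",
              object@netod_domain[1], object@netod_domain[2]))
})

#' GroundTruthConfig: parameters of the synthetic study generator
#'
#' Fully specifies a simulated film-calibration study: the true dose
#' response, scanner/pixel statistics, the repeat-scan protocol, and the
#' beam/wedge geometry. Defaults replicate the study conditions: ten
#' uniform-field strips at 1 to 5.5 Gy in 0.5 Gy steps, five wedge strips at
#' CAX doses 1 to 5 Gy, a 60 degree wedge in a 15 x 15 cm field at SSD 100 cm
#' and 5 cm depth, five repeat scans per strip at 127 dpi.
#'
#' @slot true_a,true_b,true_n true dose-response parameters (Gy, Gy, -).
#' @slot pv_unexp_mean,pv_bckg_mean mean unexposed-film and zero-light pixel
#'   values on the 16-bit scale.
#' @slot pixel_noise_rel per-scan relative Gaussian pixel noise (fraction of
#'   the pixel value).
#' @slot film_nonuniformity_rel relative sd of the low-frequency multiplicative
#'   film nonuniformity field.
#' @slot nonuniformity_corr_mm correlation length of that field (mm).
#' @slot n_repeat_scans repeat scans per strip and role.
#' @slot dpi scan resolution (dots per inch).
#' @slot seed RNG seed used by [simulateStudy()].
#' @slot geometry list: \code{fieldSizeCm}, \code{ssdCm}, \code{depthCm},
#'   \code{wedgeAngleDeg}, \code{attenuationCax}.
#' @slot penumbra_mm 80-20 penumbra width of the field edges (mm).
#' @slot wedge_dynamic_range ratio of the lateral wedge factor across the
#'   central 60 percent of the field (sets the exponential slope).
#' @slot scatter_floor out-of-field dose as a fraction of the CAX dose.
#' @slot benchmark_doses_gy nominal uniform-field doses (Gy).
#' @slot wedge_doses_gy nominal wedge CAX doses (Gy).
#' @slot benchmark_raster_px c(rows, cols) of benchmark strip rasters.
#' @slot wedge_raster_rows_px transverse rows of wedge strip rasters.
#' @slot margin_mm raster margin beyond each field edge (mm).
#' @slot output_gy_per_mu linac output calibration (Gy per MU).
#' @export
setClass("GroundTruthConfig",
  representation(
    true_a = "numeric", true_b = "numeric", true_n = "numeric",
    pv_unexp_mean = "numeric", pv_bckg_mean = "numeric",
    pixel_noise_rel = "numeric", film_nonuniformity_rel = "numeric",
    nonuniformity_corr_mm = "numeric", n_repeat_scans = "integer",
    dpi = "numeric", seed = "integer", geometry = "list",
    penumbra_mm = "numeric", wedge_dynamic_range = "numeric",
    scatter_floor = "numeric", benchmark_doses_gy = "numeric",
    wedge_doses_gy = "numeric", benchmark_raster_px = "integer",
    wedge_raster_rows_px = "integer", margin_mm = "numeric",
    output_gy_per_mu = "numeric"))

setValidity("GroundTruthConfig", function(object) {
  if (object@true_a <= 0 || object@true_b <= 0)
    return("true_a and true_b must be positive")
  if (object@true_n <= 1) return("true_n must be > 1")
  if (object@pixel_noise_rel < 0) return("pixel_noise_rel must be >= 0")
  if (object@dpi <= 0) return("dpi must be positive")
  ac <- object@geometry$attenuationCax
  if (is.null(ac) || ac <= 0 || ac >= 1)
    return("geometry$attenuationCax must lie in (0, 1)")
  if (object@n_repeat_scans < 1L) return("n_repeat_scans must be >= 1")
  if (object@wedge_dynamic_range <= 1)
    return("wedge_dynamic_range must exceed 1")
  if (object@scatter_floor < 0 || object@scatter_floor >= 1)
    return("scatter_floor must lie in [0, 1)")
  TRUE
})

#' Build a GroundTruthConfig
#'
#' All arguments default to the replicated study conditions; see
#' [GroundTruthConfig-class] for their meaning.
#'
#' @param trueA,trueB,trueN true dose-response parameters.
#' @param pvUnexpMean,pvBckgMean mean unexposed / zero-light pixel values.
#' @param pixelNoiseRel per-scan relative pixel noise.
#' @param filmNonuniformityRel relative sd of the film nonuniformity field.
#' @param nonuniformityCorrMm its correlation length (mm).
#' @param nRepeatScans repeat scans per strip and role.
#' @param dpi scan resolution.
#' @param seed RNG seed for [simulateStudy()].
#' @param fieldSizeCm,ssdCm,depthCm,wedgeAngleDeg,attenuationCax beam and
#'   wedge geometry.
#' @param penumbraMm 80-20 penumbra width (mm).
#' @param wedgeDynamicRange lateral-factor ratio over the trimmed region.
#' @param scatterFloor out-of-field relative dose.
#' @param benchmarkDosesGy uniform-field dose levels (Gy).
#' @param wedgeDosesGy wedge CAX dose levels (Gy).
#' @param benchmarkRasterPx c(rows, cols) for benchmark rasters.
#' @param wedgeRasterRowsPx transverse rows for wedge rasters.
#' @param marginMm raster margin beyond the field edges (mm).
#' @param outputGyPerMu linac output (Gy/MU).
#' @return A [GroundTruthConfig-class].
#' @examples
#' cfg <- groundTruthConfig(seed = 7L)
#' truthNetODFromDose(cfg, 4.972)
#' @export
groundTruthConfig <- function(trueA = 10, trueB = 40, trueN = 2.5,
                              pvUnexpMean = 40000, pvBckgMean = 1000,
                              pixelNoiseRel = 0.005,
                              filmNonuniformityRel = 0.003,
                              nonuniformityCorrMm = 50,
                              nRepeatScans = 5L, dpi = 127, seed = 1234L,
                              fieldSizeCm = 15, ssdCm = 100, depthCm = 5,
                              wedgeAngleDeg = 60, attenuationCax = 0.2654,
                              penumbraMm = 5, wedgeDynamicRange = 3,
                              scatterFloor = 0.02,
                              benchmarkDosesGy = seq(1, 5.5, by = 0.5),
                              wedgeDosesGy = 1:5,
                              benchmarkRasterPx = c(48L, 48L),
                              wedgeRasterRowsPx = 60L,
                              marginMm = 20,
                              outputGyPerMu = 0.01) {
  new("GroundTruthConfig",
      true_a = trueA, true_b = trueB, true_n = trueN,
      pv_unexp_mean = pvUnexpMean, pv_bckg_mean = pvBckgMean,
      pixel_noise_rel = pixelNoiseRel,
      film_nonuniformity_rel = filmNonuniformityRel,
      nonuniformity_corr_mm = nonuniformityCorrMm,
      n_repeat_scans = as.integer(nRepeatScans), dpi = dpi,
      seed = as.integer(seed),
      geometry = list(fieldSizeCm = fieldSizeCm, ssdCm = ssdCm,
                      depthCm = depthCm, wedgeAngleDeg = wedgeAngleDeg,
                      attenuationCax = attenuationCax),
      penumbra_mm = penumbraMm, wedge_dynamic_range = wedgeDynamicRange,
      scatter_floor = scatterFloor,
      benchmark_doses_gy = benchmarkDosesGy,
      wedge_doses_gy = as.numeric(wedgeDosesGy),
      benchmark_raster_px = as.integer(benchmarkRasterPx),
      wedge_raster_rows_px = as.integer(wedgeRasterRowsPx),
      margin_mm = marginMm, output_gy_per_mu = outputGyPerMu)
}

#' @rdname accessors
#' @export
setMethod("geometry", "GroundTruthConfig", function(object) object@geometry)
#' @rdname accessors
#' @export
setMethod("dpi", "GroundTruthConfig", function(object) object@dpi)

setMethod("show", "GroundTruthConfig", function(object) {
  cat(sprintf(
    "GroundTruthConfig: D = %.3g netOD + %.3g netOD^%.3g, %d repeat scans, %g dpi, seed %d\n",
    object@true_a, object@true_b, object@true_n, object@n_repeat_scans,
    object@dpi, object@seed))
  cat(sprintf("  noise: pixel %.4g rel, nonuniformity %.4g rel (corr %g mm)\n",
              object@pixel_noise_rel, object@film_nonuniformity_rel,
              object@nonuniformity_corr_mm))
  cat(sprintf("  doses: BC %s Gy; wedge CAX %s Gy\n",
              paste(object@benchmark_doses_gy, collapse = ", "),
              paste(object@wedge_doses_gy, collapse = ", ")))
})

#' FilmStudy: one simulated (or loaded) film calibration study
#'
#' @slot benchmark list of uniform-field strip sets, each a list with
#'   \code{scans} (unexposed/exposed/background stacks) and \code{dose_gy}.
#' @slot wedge list of [WedgeExposure-class] objects.
#' @slot reference the [WedgeReference-class] profile used.
#' @slot config the [GroundTruthConfig-class] that generated the study.
#' @export
setClass("FilmStudy",
  representation(benchmark = "list", wedge = "list",
                 reference = "WedgeReference", config = "GroundTruthConfig"))

setMethod("show", "FilmStudy", function(object) {
  cat(sprintf("FilmStudy: %d benchmark strips, %d wedge exposures\n",
              length(object@benchmark), length(object@wedge)))
})

#' @describeIn FilmStudy-class benchmark strip sets.
#' @param study a \code{FilmStudy}.
#' @export
benchmarkSets <- function(study) study@benchmark

#' @describeIn FilmStudy-class wedge exposures.
#' @export
wedgeExposures <- function(study) study@wedge

#' @describeIn FilmStudy-class the wedge reference profile.
#' @export
studyReference <- function(study) study@reference

#' @describeIn FilmStudy-class the generating configuration.
#' @export
studyConfig <- function(study) study@config
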