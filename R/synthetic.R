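# Study-replica scan generator: renders uniform-field (benchmark) and
# wedge-field scan triplets from a configured ground-truth dose response so
# that every pipeline stage can be exercised without real films.

#' Invert the true dose response of a generator configuration
#'
#' Finds the unique netOD >= 0 with
#' \code{true_a * netod + true_b * netod^true_n = dose} by bisection
#' (absolute netOD tolerance 1e-10); dose 0 maps to netOD 0. Vectorized.
#'
#' @param cfg a [GroundTruthConfig-class].
#' @param doseGy dose value(s) >= 0.
#' @return netOD value(s).
#' @export
truthNetODFromDose <- function(cfg, doseGy) {
  curve <- CalibrationCurve(a = cfg@true_a, b = cfg@true_b, n = cfg@true_n,
                            netod_domain = c(0, 1))
  netODFromDose(curve, doseGy)
}

# projected field span (mm) at the measurement plane
.fieldSpanMm <- function(cfg) {
  g <- cfg@geometry
  g$fieldSizeCm * 10 * (g$ssdCm + g$depthCm) / g$ssdCm
}

# lateral wedge transmission factor f(x), f(0) = 1, exponential in the
# linearly varying wedge thickness; slope set so f spans the configured
# dynamic range across the central 60% of the field
.wedgeLateralFactor <- function(cfg, xMm) {
  k <- log(cfg@wedge_dynamic_range) / (0.6 * .fieldSpanMm(cfg))
  exp(-k * xMm)
}

# sigmoid field-border rolloff with the configured 80-20 penumbra width
.fieldRolloff <- function(cfg, xMm) {
  half <- .fieldSpanMm(cfg) / 2
  w <- cfg@penumbra_mm / (2 * log(4))
  stats::plogis((xMm + half) / w) * stats::plogis((half - xMm) / w)
}

# relative lateral dose profile of the wedge field, normalized so the CAX
# value is exactly 1 (for narrow fields the penumbra tails are not fully
# negligible at the CAX)
.wedgeDoseRel <- function(cfg, xMm) {
  s <- cfg@scatter_floor
  raw <- function(x) s + (1 - s) * .fieldRolloff(cfg, x) *
    .wedgeLateralFactor(cfg, x)
  raw(xMm) / raw(0)
}

#' Synthetic wedge dose field and matching reference profile
#'
#' Separable model: along the wedge axis an exponential lateral factor
#' (f(0) = 1) spanning the configured dynamic range, multiplied by a sigmoid
#' border rolloff of the configured penumbra width, on top of a constant
#' out-of-field scatter floor; flat in the transverse direction (the strip
#' lies well inside the field). The identical lateral profile is emitted as
#' the [WedgeReference-class], so pipeline tests are self-consistent by
#' construction. The raster is centered on the CAX (odd column count, CAX
#' exactly on a pixel), with \code{shiftMm} the field can be displaced to
#' probe translation tolerance.
#'
#' @param cfg a [GroundTruthConfig-class].
#' @param dCaxGy nominal CAX dose (Gy), > 0.
#' @param shiftMm lateral displacement of the field within the raster (mm).
#' @return list with \code{raster} (dose matrix, Gy), \code{reference}
#'   (a [WedgeReference-class]) and \code{x_mm} (column positions relative
#'   to the raster's CAX pixel).
#' @export
wedgeDoseField <- function(cfg, dCaxGy, shiftMm = 0) {
  if (dCaxGy <= 0) .stopf("domainError", "CAX dose must be positive")
  span <- .fieldSpanMm(cfg)
  pxmm <- MM_PER_INCH / cfg@dpi
  halfcols <- ceiling((span / 2 + cfg@margin_mm) / pxmm)
  if (abs(shiftMm) > cfg@margin_mm / 2)
    .stopf("dimensionError", "field shift exceeds the raster margin")
  x <- (-halfcols:halfcols) * pxmm
  rel <- .wedgeDoseRel(cfg, x - shiftMm)
  rows <- cfg@wedge_raster_rows_px
  raster <- matrix(rel * dCaxGy, nrow = rows, ncol = length(x), byrow = TRUE)
  refx <- x
  ref <- WedgeReference(refx, .wedgeDoseRel(cfg, refx),
                        attenuation_cax = cfg@geometry$attenuationCax,
                        geometry = cfg@geometry)
  list(raster = raster, reference = ref, x_mm = x)
}

#' Synthetic uniform (benchmark) dose field
#'
#' A uniform-field calibration strip sits entirely inside the open field, so
#' its raster is a constant dose.
#'
#' @param cfg a [GroundTruthConfig-class].
#' @param doseGy nominal dose (Gy), >= 0.
#' @return dose matrix (Gy) of size \code{benchmark_raster_px}.
#' @export
uniformDoseField <- function(cfg, doseGy) {
  matrix(doseGy, cfg@benchmark_raster_px[1], cfg@benchmark_raster_px[2])
}

# low-frequency multiplicative nonuniformity field: Gaussian coarse grid at
# the configured correlation length, bilinearly upsampled
.smoothRandomField <- function(rows, cols, dpi, corrMm, sd) {
  stepPx <- max(2, corrMm * dpi / MM_PER_INCH)
  nr <- ceiling((rows - 1) / stepPx) + 2L
  nc <- ceiling((cols - 1) / stepPx) + 2L
  z <- matrix(stats::rnorm(nr * nc, 0, sd), nr, nc)
  u <- 1 + (seq_len(rows) - 1) / stepPx
  v <- 1 + (seq_len(cols) - 1) / stepPx
  zr <- apply(z, 2, function(col) stats::approx(seq_len(nr), col, xout = u)$y)
  zr <- matrix(zr, nrow = rows)
  t(apply(zr, 1, function(row) stats::approx(seq_len(nc), row, xout = v)$y))
}

#' Render the scan triplet of one film exposure
#'
#' Builds the mean pixel-value maps from the ground truth -- unexposed film
#' at \code{pv_unexp_mean} modulated by the film's low-frequency
#' nonuniformity field, exposed film attenuated according to the true netOD
#' of the local dose (the same film, hence the same nonuniformity
#' realization), zero-light background at \code{pv_bckg_mean} -- and draws
#' \code{n_repeat_scans} repeat scans of each with independent Gaussian
#' pixel noise of sd \code{pixel_noise_rel * PV}, clipped to the 16-bit
#' range and rounded. A zero-noise configuration returns the analytic
#' expectation maps unquantized, which is what exactness round-trip checks
#' rely on; quantization to integers is a property of the noisy scanner
#' model and of rasters written to disk. Randomness comes from the current
#' RNG state; [simulateStudy()] seeds it once per study.
#'
#' @param cfg a [GroundTruthConfig-class].
#' @param doseRaster dose matrix (Gy).
#' @return list with \code{unexposed}, \code{exposed}, \code{background}:
#'   each a list of \code{n_repeat_scans} [ScanImage-class] objects.
#' @export
renderScanTriplet <- function(cfg, doseRaster) {
  r <- nrow(doseRaster); cns <- ncol(doseRaster)
  u <- if (cfg@film_nonuniformity_rel > 0)
    .smoothRandomField(r, cns, cfg@dpi, cfg@nonuniformity_corr_mm,
                       cfg@film_nonuniformity_rel)
  else matrix(0, r, cns)
  unexpMean <- cfg@pv_unexp_mean * (1 + u)
  # dose varies along one axis only in practice; invert unique values once
  dv <- as.vector(doseRaster)
  ud <- unique(dv)
  nodU <- truthNetODFromDose(cfg, ud)
  nod <- matrix(nodU[match(dv, ud)], r, cns)
  expMean <- cfg@pv_bckg_mean + (unexpMean - cfg@pv_bckg_mean) * 10^(-nod)
  bckgMean <- matrix(cfg@pv_bckg_mean, r, cns)
  noisy <- function(meanMap, role) {
    lapply(seq_len(cfg@n_repeat_scans), function(i) {
      pv <- if (cfg@pixel_noise_rel > 0) {
        raw <- meanMap + stats::rnorm(length(meanMap),
                                      sd = cfg@pixel_noise_rel * meanMap)
        .rhaz(pmin(pmax(raw, 0), 65535))
      } else meanMap
      ScanImage(matrix(pv, r, cns), dpi = cfg@dpi, channel = "red",
                role = role)
    })
  }
  list(unexposed = noisy(unexpMean, "unexposed"),
       exposed = noisy(expMean, "exposed"),
       background = noisy(bckgMean, "background"))
}

#' Simulate a complete film-calibration study
#'
#' Seeds the RNG from \code{cfg@seed} and generates the full study: one
#' uniform-field scan triplet per benchmark dose level and one wedge-field
#' triplet per wedge CAX dose, plus the wedge reference profile. With
#' \code{dir} the study is also written to disk: 16-bit RGB TIFF scans (red
#' plane carries the signal, green/blue copies), the reference profile as
#' CSV with a YAML sidecar (attenuation and geometry) and a JSON manifest
#' holding the full generator configuration. Two runs with the same seed
#' produce byte-identical outputs.
#'
#' @param cfg a [GroundTruthConfig-class].
#' @param dir optional output directory (created if missing).
#' @return A [FilmStudy-class] (invisibly when writing to disk).
#' @seealso [loadStudy()]
#' @export
simulateStudy <- function(cfg, dir = NULL) {
  set.seed(cfg@seed)
  benchmark <- lapply(cfg@benchmark_doses_gy, function(d) {
    list(scans = renderScanTriplet(cfg, uniformDoseField(cfg, d)),
         dose_gy = d)
  })
  ref <- NULL
  wedge <- lapply(cfg@wedge_doses_gy, function(d) {
    wf <- wedgeDoseField(cfg, d)
    ref <<- wf$reference
    WedgeExposure(renderScanTriplet(cfg, wf$raster), d_cax_gy = d, axis = "x")
  })
  study <- new("FilmStudy", benchmark = benchmark, wedge = wedge,
               reference = ref, config = cfg)
  if (!is.null(dir)) {
    writeStudy(study, dir)
    return(invisible(study))
  }
  study
}
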