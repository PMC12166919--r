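#' Net optical density of background-corrected pixel values
#'
#' The film's dose-response signal: the base-10 log ratio of
#' background-corrected transmitted pixel values before and after exposure,
#' \deqn{netOD = \log_{10}\frac{PV_{unexp} - PV_{bckg}}{PV_{exp} - PV_{bckg}}.}
#' Vectorized over its arguments.
#'
#' @param pvUnexp unexposed-film pixel value(s).
#' @param pvExp exposed-film pixel value(s).
#' @param pvBckg zero-light background pixel value(s).
#' @return netOD value(s).
#' @examples
#' netOpticalDensity(40000, 20000, 1000)  # log10(39000/19000)
#' @export
netOpticalDensity <- function(pvUnexp, pvExp, pvBckg) {
  num <- pvUnexp - pvBckg
  den <- pvExp - pvBckg
  if (any(num <= 0) || any(den <= 0))
    .stopf("domainError",
           "netOD undefined: background-corrected PV must be positive (saturated/over-dark film or bad background)")
  log10(num / den)
}

#' One-sigma netOD uncertainty by first-order error propagation
#'
#' Propagates the pixel-value spreads of the three scans through the netOD
#' expression:
#' \deqn{\sigma_{netOD} = \frac{1}{\ln 10}\sqrt{
#'   \frac{\sigma_{unexp}^2 + \sigma_{bckg}^2}{(PV_{unexp}-PV_{bckg})^2} +
#'   \frac{\sigma_{exp}^2 + \sigma_{bckg}^2}{(PV_{exp}-PV_{bckg})^2}}.}
#'
#' @param pvUnexp,pvExp,pvBckg pixel values as in [netOpticalDensity()].
#' @param sdUnexp,sdExp,sdBckg one-sigma pixel-value spreads (>= 0).
#' @return one-sigma netOD uncertainty.
#' @export
netODUncertainty <- function(pvUnexp, sdUnexp, pvExp, sdExp,
                             pvBckg, sdBckg) {
  num <- pvUnexp - pvBckg
  den <- pvExp - pvBckg
  if (any(num <= 0) || any(den <= 0))
    .stopf("domainError", "netOD uncertainty undefined outside the netOD domain")
  if (any(c(sdUnexp, sdExp, sdBckg) < 0))
    .stopf("domainError", "pixel-value spreads must be >= 0")
  (1 / log(10)) * sqrt((sdUnexp^2 + sdBckg^2) / num^2 +
                       (sdExp^2 + sdBckg^2) / den^2)
}

#' Per-pixel netOD map with propagated uncertainty
#'
#' Applies [netOpticalDensity()] element-wise to three reduced rasters of
#' identical shape and dpi. Pixels at which the log argument is non-positive
#' (for instance saturated film where \code{exp <= bckg}) are masked, not
#' fatal; neighbors are unaffected. The per-pixel uncertainty uses the
#' local pixel-value spread over a 1 x 1 mm neighborhood of each raster
#' (sample sd, reflect padding) propagated through the netOD expression.
#'
#' @param unexp,exp,bckg [ScanImage-class] rasters of identical shape/dpi.
#' @param roiMm side length (mm) of the local-spread neighborhood.
#' @return A [NetODMap-class].
#' @export
netODMap <- function(unexp, exp, bckg, roiMm = 1) {
  pu <- pixels(unexp); pe <- pixels(exp); pb <- pixels(bckg)
  if (!identical(dim(pu), dim(pe)) || !identical(dim(pu), dim(pb)))
    .stopf("dimensionError", "netODMap rasters must share dimensions")
  if (dpi(unexp) != dpi(exp) || dpi(unexp) != dpi(bckg))
    .stopf("dimensionError", "netODMap rasters must share dpi")
  num <- pu - pb
  den <- pe - pb
  bad <- num <= 0 | den <= 0
  nod <- array(NA_real_, dim(pu))
  nod[!bad] <- log10(num[!bad] / den[!bad])
  w <- max(1L, as.integer(.rhaz(.mmToPx(roiMm, dpi(unexp)))))
  su <- .localSD(pu, w); se <- .localSD(pe, w); sb <- .localSD(pb, w)
  sig <- array(NA_real_, dim(pu))
  sig[!bad] <- (1 / log(10)) *
    sqrt((su[!bad]^2 + sb[!bad]^2) / num[!bad]^2 +
         (se[!bad]^2 + sb[!bad]^2) / den[!bad]^2)
  NetODMap(netod = nod, sigma = sig, dpi = dpi(unexp), mask = bad)
}
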