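#' Fit the film dose response D = a netOD + b netOD^n
#'
#' Least-squares fit of the two-term power-law response with the exponent
#' held fixed, using the Levenberg-Marquardt algorithm
#' (\code{minpack.lm::nlsLM}). Residuals are unweighted in dose by default;
#' netOD uncertainties are carried along for uncertainty budgets only. A
#' weighted mode (weights \code{1/sigma_netod^2}) is available. The fit is
#' initialized deterministically: \code{a0} is the dose/netOD slope through
#' the two lowest-netOD points and \code{b0 = 0}.
#'
#' @param points data frame with columns \code{netod}, \code{sigma_netod},
#'   \code{dose_gy}; at least 3 rows, netOD values not all equal.
#' @param nFixed the fixed exponent (default 2.5).
#' @param weighted logical; if TRUE, weight residuals by
#'   \code{1/sigma_netod^2} (requires all sigma > 0).
#' @return A [CalibrationCurve-class]; \code{netod_domain} is the observed
#'   netOD range.
#' @examples
#' x <- seq(0.05, 0.5, length.out = 10)
#' pts <- data.frame(netod = x, sigma_netod = 0, dose_gy = 10 * x + 40 * x^2.5)
#' fitCalibration(pts)
#' @export
fitCalibration <- function(points, nFixed = 2.5, weighted = FALSE) {
  if (!all(c("netod", "dose_gy") %in% names(points)))
    .stopf("fitError", "points must contain netod and dose_gy columns")
  if (is.null(points$sigma_netod)) points$sigma_netod <- 0
  if (nrow(points) < 3L)
    .stopf("fitError", "need at least 3 calibration points, got %d",
           nrow(points))
  x <- points$netod; y <- points$dose_gy
  if (length(unique(x)) < 2L)
    .stopf("fitError", "netOD values are all equal; design is rank deficient")
  if (nFixed <= 1) .stopf("parameterError", "fixed exponent must exceed 1")
  ord <- order(x)
  lo <- ord[1:2]
  a0 <- if (diff(x[lo]) != 0) diff(y[lo]) / diff(x[lo]) else y[lo[1]] / x[lo[1]]
  if (!is.finite(a0) || a0 <= 0) a0 <- max(y) / max(x)
  w <- rep(1, length(x))
  if (weighted) {
    if (any(points$sigma_netod <= 0))
      .stopf("fitError", "weighted fit requires positive sigma_netod")
    w <- 1 / points$sigma_netod^2
  }
  dat <- data.frame(x = x, y = y)
  lmFit <- function(start) minpack.lm::nlsLM(
    y ~ a * x + b * x^nFixed, data = dat, start = start, weights = w,
    control = minpack.lm::nls.lm.control(ftol = 1e-12, ptol = 1e-12,
                                         maxiter = 1000))
  # with n fixed the model is linear in (a, b); when the iterative fit lands
  # on an exact zero-residual optimum (noiseless data) its gradient test
  # degenerates, and the closed-form linear least-squares solution is used
  linearFit <- function() {
    X <- cbind(a = x, b = x^nFixed)
    lf <- stats::lm(y ~ 0 + X, weights = w)
    sm <- suppressWarnings(summary(lf))  # zero-residual fits are expected here
    co <- sm$coefficients
    rownames(co) <- sub("^X", "", rownames(co))
    list(coef = co, iterations = 0L, residual_sd = sm$sigma)
  }
  fit <- tryCatch(lmFit(list(a = a0, b = 0)), error = function(e) NULL)
  res <- if (is.null(fit)) {
    tryCatch(linearFit(), error = function(e)
      .stopf("fitError", "calibration fit failed: %s", conditionMessage(e)))
  } else {
    if (!isTRUE(fit$convInfo$isConv))
      .stopf("fitError", "calibration fit did not converge after %d iterations",
             fit$convInfo$finIter)
    list(coef = summary(fit)$coefficients,
         iterations = fit$convInfo$finIter,
         residual_sd = summary(fit)$sigma)
  }
  co <- res$coef
  if (any(!is.finite(co[, "Std. Error"])))
    .stopf("fitError", "rank-deficient fit: parameter covariance undefined")
  CalibrationCurve(
    a = co["a", "Estimate"], b = co["b", "Estimate"], n = nFixed,
    sigma_a = co["a", "Std. Error"], sigma_b = co["b", "Std. Error"],
    netod_domain = range(x),
    fit_meta = list(n_points = nrow(points),
                    iterations = res$iterations,
                    residual_sd = res$residual_sd,
                    weighted = weighted))
}

#' Evaluate a calibration curve
#'
#' Computes \code{a * netod + b * netod^n}. Evaluation outside the fitted
#' netOD domain is permitted but flagged: the result carries a logical
#' attribute \code{"extrapolated"}.
#'
#' @param curve a [CalibrationCurve-class].
#' @param netod netOD value(s), >= 0.
#' @return dose(s) in Gy with attribute \code{extrapolated}.
#' @export
doseFromNetOD <- function(curve, netod) {
  if (any(netod < 0)) .stopf("domainError", "netOD must be >= 0")
  d <- coefA(curve) * netod + coefB(curve) * netod^coefN(curve)
  dom <- netODDomain(curve)
  attr(d, "extrapolated") <- netod < dom[1] | netod > dom[2]
  d
}

#' Invert a calibration curve by bisection
#'
#' The forward map is strictly increasing for positive coefficients, so the
#' netOD producing a given dose is found by bisection to an absolute netOD
#' tolerance of 1e-10. Vectorized over doses; dose 0 maps to netOD 0.
#'
#' @param curve a [CalibrationCurve-class] with \code{a, b > 0}.
#' @param doseGy dose value(s), >= 0.
#' @param tol bisection tolerance in netOD.
#' @return netOD value(s).
#' @export
netODFromDose <- function(curve, doseGy, tol = 1e-10) {
  if (any(doseGy < 0)) .stopf("domainError", "dose must be >= 0")
  a <- coefA(curve); b <- coefB(curve); n <- coefN(curve)
  f <- function(x) a * x + b * x^n
  hi <- 1
  while (f(hi) < max(doseGy)) hi <- hi * 2
  lov <- numeric(length(doseGy)); hiv <- rep(hi, length(doseGy))
  while (max(hiv - lov) > tol) {
    mid <- (lov + hiv) / 2
    below <- f(mid) < doseGy
    lov[below] <- mid[below]
    hiv[!below] <- mid[!below]
  }
  out <- (lov + hiv) / 2
  out[doseGy == 0] <- 0
  out
}

#' Relative experimental dose uncertainty (percent)
#'
#' The netOD measurement uncertainty propagated through the calibration
#' curve: \code{|dD/dnetOD| * sigma_netod / D * 100} with
#' \code{dD/dnetOD = a + n b netOD^(n-1)}.
#'
#' @param curve a [CalibrationCurve-class].
#' @param netod netOD value(s); the implied dose must be positive.
#' @param sigmaNetod one-sigma netOD uncertainty(ies).
#' @return percent uncertainty(ies).
#' @export
experimentalUncertaintyPct <- function(curve, netod, sigmaNetod) {
  d <- as.numeric(doseFromNetOD(curve, netod))
  if (any(d <= 0))
    .stopf("domainError", "experimental uncertainty undefined at zero dose")
  a <- coefA(curve); b <- coefB(curve); n <- coefN(curve)
  deriv <- a + n * b * netod^(n - 1)
  sqrt(deriv^2 * sigmaNetod^2) / d * 100
}

#' Relative fit dose uncertainty (percent)
#'
#' The parameter-covariance contribution:
#' \code{sqrt(netOD^2 sigma_a^2 + netOD^(2n) sigma_b^2) / D * 100}.
#'
#' @inheritParams experimentalUncertaintyPct
#' @return percent uncertainty(ies).
#' @export
fitUncertaintyPct <- function(curve, netod) {
  d <- as.numeric(doseFromNetOD(curve, netod))
  if (any(d <= 0))
    .stopf("domainError", "fit uncertainty undefined at zero dose")
  n <- coefN(curve)
  sqrt(netod^2 * sigmaA(curve)^2 + netod^(2 * n) * sigmaB(curve)^2) / d * 100
}

#' Total relative dose uncertainty (percent)
#'
#' Quadrature sum of the experimental and fit components.
#'
#' @param sigmaExpPct experimental component(s), percent, >= 0.
#' @param sigmaFitPct fit component(s), percent, >= 0.
#' @return total percent uncertainty(ies).
#' @examples
#' totalUncertaintyPct(3, 4)  # 5
#' @export
totalUncertaintyPct <- function(sigmaExpPct, sigmaFitPct) {
  if (any(sigmaExpPct < 0) || any(sigmaFitPct < 0))
    .stopf("domainError", "uncertainty components must be >= 0")
  sqrt(sigmaExpPct^2 + sigmaFitPct^2)
}

#' Full uncertainty budget at given netOD values
#'
#' @param curve a [CalibrationCurve-class].
#' @param netod netOD values.
#' @param sigmaNetod matching one-sigma netOD uncertainties.
#' @return data frame with \code{sigma_exp_pct}, \code{sigma_fit_pct},
#'   \code{sigma_total_pct}.
#' @export
uncertaintyBudget <- function(curve, netod, sigmaNetod) {
  e <- experimentalUncertaintyPct(curve, netod, sigmaNetod)
  f <- fitUncertaintyPct(curve, netod)
  data.frame(sigma_exp_pct = e, sigma_fit_pct = f,
             sigma_total_pct = totalUncertaintyPct(e, f))
}

#' Percent deviation of a wedge-calibrated dose from the benchmark
#'
#' \code{|D_BC - D_PW| / D_BC * 100}, vectorized.
#'
#' @param dBC benchmark dose(s), > 0.
#' @param dPW wedge-calibration dose(s).
#' @return percent deviation(s).
#' @export
deviationPct <- function(dBC, dPW) {
  if (any(dBC <= 0)) .stopf("domainError", "benchmark dose must be positive")
  abs(dBC - dPW) / dBC * 100
}

#' netOD of one uniform-field strip set with propagated uncertainty
#'
#' Reduces the unexposed, exposed and background scan stacks, takes the mean
#' red-channel pixel value over an ROI at the strip center of each reduced
#' raster, and propagates the ROI pixel spreads through the netOD
#' expression. Means come from the fully reduced (Wiener-filtered) rasters;
#' spreads from the median-filtered averages before Wiener filtering (see
#' [reduceScanStack()]), the conservative convention (the ROI sd itself, not
#' the standard error of the mean).
#'
#' @param scans list with \code{unexposed}, \code{exposed},
#'   \code{background} stacks of [ScanImage-class] objects.
#' @param roiMm ROI side length (mm).
#' @return one-row data frame: \code{netod}, \code{sigma_netod}.
#' @export
stripNetOD <- function(scans, roiMm = 1) {
  stats <- lapply(c("unexposed", "exposed", "background"), function(role) {
    full <- reduceScanStack(scans[[role]])
    avg <- reduceScanStack(scans[[role]], applyWiener = FALSE)
    list(mean = centerRoiMean(full, c(roiMm, roiMm))@meanPV,
         sd = centerRoiMean(avg, c(roiMm, roiMm))@sdPV)
  })
  names(stats) <- c("u", "e", "b")
  data.frame(
    netod = netOpticalDensity(stats$u$mean, stats$e$mean, stats$b$mean),
    sigma_netod = netODUncertainty(stats$u$mean, stats$u$sd, stats$e$mean,
                                   stats$e$sd, stats$b$mean, stats$b$sd))
}

#' Benchmark calibration from uniform-field strip sets
#'
#' Runs the full conventional chain: each strip set's unexposed, exposed and
#' background stacks are reduced ([reduceScanStack()]), the mean red-channel
#' pixel value of a 1 x 1 mm ROI at the strip center yields one netOD with
#' propagated uncertainty, and the pooled points are fitted with
#' [fitCalibration()]. Per-point uncertainty budgets are evaluated on the
#' fitted curve.
#'
#' @param stripSets list of strip sets; each a list with \code{scans} (a list
#'   with \code{unexposed}, \code{exposed}, \code{background} stacks of
#'   [ScanImage-class]) and \code{dose_gy}.
#' @param roiMm ROI side length (mm), default 1.
#' @param nFixed fixed exponent for the fit.
#' @param weighted passed to [fitCalibration()].
#' @return list with \code{curve} ([CalibrationCurve-class]), \code{points}
#'   (data frame netod/sigma_netod/dose_gy) and \code{budget} (data frame
#'   from [uncertaintyBudget()]).
#' @export
benchmarkCalibration <- function(stripSets, roiMm = 1, nFixed = 2.5,
                                 weighted = FALSE) {
  pts <- lapply(stripSets, function(set) {
    cbind(stripNetOD(set$scans, roiMm = roiMm),
          data.frame(dose_gy = set$dose_gy))
  })
  points <- do.call(rbind, pts)
  points <- points[order(points$netod), , drop = FALSE]
  curve <- fitCalibration(points, nFixed = nFixed, weighted = weighted)
  budget <- uncertaintyBudget(curve, points$netod, points$sigma_netod)
  list(curve = curve, points = points, budget = budget)
}
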