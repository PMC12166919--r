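mkRef <- function() {
  x <- seq(-100, 100, by = 0.5)
  WedgeReference(x, exp(-0.0116 * x),
                 attenuation_cax = 0.2654,
                 geometry = list(fieldSizeCm = 15, ssdCm = 100, depthCm = 5,
                                 wedgeAngleDeg = 60))
}

test_that("dose-profile estimation is linear interpolation times D_CAX", {
  ref <- mkRef()
  # homogeneity of degree 1 in the CAX dose
  p1 <- estimateDoseProfile(ref, 1, seq(-40, 40, by = 0.7))
  p3 <- estimateDoseProfile(ref, 3, seq(-40, 40, by = 0.7))
  expect_equal(p3$dose_gy, 3 * p1$dose_gy, tolerance = 1e-12)
  # CAX normalization
  expect_equal(estimateDoseProfile(ref, 2.5, 0)$dose_gy, 2.5)
  # on the reference grid there is no interpolation error
  on <- estimateDoseProfile(ref, 2, positions(ref))
  expect_equal(on$dose_gy, doseRel(ref) * 2, tolerance = 1e-12)
  expect_error(estimateDoseProfile(ref, 1, c(0, 150)),
               class = "extrapolationError")
})

test_that("attenuation bookkeeping is exact", {
  expect_equal(attenuationCoefficient(0.5308, 2.0), 0.2654)
  expect_equal(attenuationCoefficient(1.7, 1.7), 1)
  expect_equal(wedgedMU(2, 0.01, 0.2654), 2 / (0.01 * 0.2654))
  expect_error(attenuationCoefficient(-1, 2), class = "domainError")
  expect_error(wedgedMU(2, 0.01, 1.2), class = "domainError")
})

test_that("profile pairing interpolates doses at netOD positions", {
  ref <- mkRef()
  dp <- estimateDoseProfile(ref, 2, positions(ref))
  x <- seq(-30, 30, by = 0.5)
  nod <- NetODProfile(x, 0.4 * exp(-0.0116 * x), rep(0.001, length(x)))
  pts <- pairProfiles(dp, nod)
  expect_equal(pts$dose_gy, 2 * exp(-0.0116 * x), tolerance = 1e-6)
  expect_equal(pts$netod, netOD(nod))

  # half-sample offset: doses linearly interpolated (brute force)
  xo <- x + 0.25
  nodo <- NetODProfile(xo, 0.4 * exp(-0.0116 * xo))
  ptso <- pairProfiles(dp, nodo)
  brute <- vapply(xo, function(p) {
    i <- findInterval(p, dp$position_mm)
    x0 <- dp$position_mm[i]; x1 <- dp$position_mm[i + 1]
    dp$dose_gy[i] + (dp$dose_gy[i + 1] - dp$dose_gy[i]) * (p - x0) / (x1 - x0)
  }, numeric(1))
  expect_equal(ptso$dose_gy, brute, tolerance = 1e-12)

  # monotone in, monotone out
  expect_true(all(diff(pts$dose_gy[order(pts$netod)]) > 0))

  far <- NetODProfile(x + 500, netOD(nod))
  expect_error(pairProfiles(dp, far), class = "registrationError")
})

test_that("noiseless single-gradient calibration recovers the truth", {
  study <- noiselessStudy()
  cfg <- studyConfig(study)
  truth <- CalibrationCurve(a = 10, b = 40, n = 2.5, netod_domain = c(0, 1))
  wc <- wedgeCalibration(wedgeExposures(study)[1], studyReference(study))
  expect_identical(coefN(wc$curve), 2.5)
  expect_gt(nrow(wc$points), 400)  # hundreds of points from one strip
  xs <- seq(netODDomain(wc$curve)[1], netODDomain(wc$curve)[2],
            length.out = 100)
  relDev <- abs(as.numeric(doseFromNetOD(wc$curve, xs)) /
                as.numeric(doseFromNetOD(truth, xs)) - 1)
  expect_lt(max(relDev), 1e-3)
})

test_that("noiseless wedge and benchmark curves agree on the shared domain", {
  study <- noiselessStudy()
  bc <- benchmarkCalibration(benchmarkSets(study))
  wc <- wedgeCalibration(wedgeExposures(study)[1], studyReference(study))
  lo <- max(netODDomain(bc$curve)[1], netODDomain(wc$curve)[1])
  hi <- min(netODDomain(bc$curve)[2], netODDomain(wc$curve)[2])
  xs <- seq(lo, hi, length.out = 100)
  relDev <- abs(as.numeric(doseFromNetOD(wc$curve, xs)) /
                as.numeric(doseFromNetOD(bc$curve, xs)) - 1)
  expect_lt(max(relDev), 0.001)  # 0.1 %
})

test_that("pooled gradients span at least a single gradient's domain", {
  study <- noiselessStudy()
  one <- wedgeCalibration(wedgeExposures(study)[1], studyReference(study))
  all5 <- wedgeCalibration(wedgeExposures(study), studyReference(study))
  expect_lte(netODDomain(all5$curve)[1], netODDomain(one$curve)[1])
  expect_gte(netODDomain(all5$curve)[2], netODDomain(one$curve)[2])
})

test_that("duplicating an exposure leaves the unweighted fit unchanged", {
  study <- noiselessStudy()
  e <- wedgeExposures(study)[[2]]
  ref <- studyReference(study)
  one <- wedgeCalibration(list(e), ref)
  two <- wedgeCalibration(list(e, e), ref)
  expect_equal(coefA(two$curve), coefA(one$curve), tolerance = 1e-8)
  expect_equal(coefB(two$curve), coefB(one$curve), tolerance = 1e-8)
})

test_that("the pipeline tolerates field translation inside the raster", {
  cfg <- noiselessConfig()
  geo <- geometry(studyReference(noiselessStudy()))
  prof <- function(shift) {
    wf <- wedgeDoseField(cfg, 3, shiftMm = shift)
    ex <- WedgeExposure(renderScanTriplet(cfg, wf$raster), 3, "x")
    extractWedgeProfile(ex, geometry = geo)
  }
  p0 <- prof(0)
  for (s in c(-5, 3.7, 5)) {
    ps <- prof(s)
    lo <- max(min(positions(p0)), min(positions(ps)))
    hi <- min(max(positions(p0)), max(positions(ps)))
    xs <- seq(lo, hi, length.out = 150)
    y0 <- approx(positions(p0), netOD(p0), xs)$y
    ys <- approx(positions(ps), netOD(ps), xs)$y
    expect_lt(max(abs(ys / y0 - 1)), 0.005)  # < 0.5 % point-wise
  }
})

test_that("benchmark comparison reports per-point deviations and flags", {
  truth <- CalibrationCurve(a = 10, b = 40, n = 2.5,
                            netod_domain = c(0.05, 0.45))
  nods <- seq(0.08, 0.32, length.out = 10)
  bcPts <- data.frame(netod = nods,
                      dose_gy = as.numeric(doseFromNetOD(truth, nods)))
  dev0 <- compareToBenchmark(truth, bcPts)
  expect_equal(nrow(dev0), 10L)
  expect_lt(max(dev0$deviation_pct), 1e-10)
  expect_false(any(dev0$extrapolated))

  # doubled a: deviation tends to 100 * a * netod / D at small netOD
  doubled <- CalibrationCurve(a = 20, b = 40, n = 2.5,
                              netod_domain = c(0.05, 0.45))
  small <- data.frame(netod = 1e-4,
                      dose_gy = as.numeric(doseFromNetOD(truth, 1e-4)))
  dv <- compareToBenchmark(doubled, small)
  expect_equal(dv$deviation_pct,
               100 * (10 * 1e-4) / small$dose_gy, tolerance = 1e-4)
  expect_true(dv$extrapolated)
})
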