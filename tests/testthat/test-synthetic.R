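test_that("the truth inversion is the exact inverse of the response", {
  cfg <- groundTruthConfig(seed = 1L)
  expect_equal(truthNetODFromDose(cfg, 0), 0)
  d <- 10 * 0.3 + 40 * 0.3^2.5  # about 4.972 Gy
  expect_equal(truthNetODFromDose(cfg, d), 0.3, tolerance = 1e-8)
  doses <- c(0.25, 0.9, 2.2, 4.7, 6)
  nods <- truthNetODFromDose(cfg, doses)
  expect_equal(10 * nods + 40 * nods^2.5, doses, tolerance = 1e-8)
})

test_that("the wedge dose field is normalized, linear and monotone", {
  cfg <- groundTruthConfig(seed = 1L)
  wf1 <- wedgeDoseField(cfg, 1)
  wf2 <- wedgeDoseField(cfg, 2)
  cax <- (ncol(wf1$raster) + 1L) / 2L
  expect_lt(abs(wf1$raster[1, cax] - 1), 1e-9)
  expect_lt(abs(wf2$raster[1, cax] - 2), 1e-9)
  expect_equal(wf2$raster, 2 * wf1$raster, tolerance = 1e-12)
  # monotone decreasing across the field interior
  inner <- abs(wf1$x_mm) < 0.4 * 157.5
  expect_true(all(diff(wf1$raster[1, inner]) < 0))
  # emitted reference matches the raster profile exactly
  expect_equal(wf1$raster[1, ], doseRel(wf1$reference), tolerance = 1e-12)
  expect_error(wedgeDoseField(cfg, 1, shiftMm = 50), class = "dimensionError")
})

test_that("zero-dose renders are compatible with zero netOD", {
  cfg <- groundTruthConfig(seed = 2L, benchmarkRasterPx = c(32L, 32L))
  set.seed(2)
  tri <- renderScanTriplet(cfg, uniformDoseField(cfg, 0))
  pt <- stripNetOD(tri)
  expect_lt(abs(pt$netod), 3 * pt$sigma_netod)
})

test_that("a noiseless render round-trips netOD through the pipeline", {
  cfg <- noiselessConfig(seed = 3L, benchmarkRasterPx = c(32L, 32L))
  tri <- renderScanTriplet(cfg, uniformDoseField(cfg, 3.5))
  m <- netODMap(reduceScanStack(tri$unexposed), reduceScanStack(tri$exposed),
                reduceScanStack(tri$background))
  expect_lt(max(abs(netOD(m) - truthNetODFromDose(cfg, 3.5))), 1e-6)
})

test_that("renders are deterministic under a fixed seed", {
  cfg <- groundTruthConfig(seed = 4L, benchmarkRasterPx = c(24L, 24L))
  set.seed(99)
  t1 <- renderScanTriplet(cfg, uniformDoseField(cfg, 2))
  set.seed(99)
  t2 <- renderScanTriplet(cfg, uniformDoseField(cfg, 2))
  expect_identical(pixels(t1$exposed[[3]]), pixels(t2$exposed[[3]]))
  f1 <- withr::local_tempfile(fileext = ".tif")
  f2 <- withr::local_tempfile(fileext = ".tif")
  saveScan(t1$exposed[[3]], f1)
  saveScan(t2$exposed[[3]], f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("generator and densitometry round-trip within 3 sigma", {
  cfg <- groundTruthConfig(seed = 5L, benchmarkRasterPx = c(32L, 32L))
  set.seed(5)
  doses <- rep(c(0.25, 0.8, 1.7, 3.1, 4.4, 6), times = 6)
  inside <- vapply(doses, function(d) {
    tri <- renderScanTriplet(cfg, uniformDoseField(cfg, d))
    pt <- stripNetOD(tri)
    abs(pt$netod - truthNetODFromDose(cfg, d)) <= 3 * pt$sigma_netod
  }, logical(1))
  expect_gte(mean(inside), 0.95)
})

test_that("simulateStudy produces the study layout and round-trips disk", {
  cfg <- tinyConfig(seed = 12L)
  dir <- withr::local_tempdir()
  study <- simulateStudy(cfg, dir = dir)
  expect_length(benchmarkSets(study), 4L)
  expect_length(wedgeExposures(study), 1L)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  expect_true(file.exists(file.path(dir, "reference.csv")))
  expect_true(file.exists(file.path(dir, "reference.yaml")))

  back <- loadStudy(dir)
  # manifest round-trips to an identical configuration
  expect_equal(wedgecal:::.cfgToList(studyConfig(back)),
               wedgecal:::.cfgToList(cfg))
  # rasters survive the 16-bit disk round trip exactly (noisy PVs are integers)
  expect_equal(pixels(benchmarkSets(back)[[2]]$scans$exposed[[1]]),
               pixels(benchmarkSets(study)[[2]]$scans$exposed[[1]]))
  ref <- studyReference(back)
  expect_equal(attenuationCAX(ref), 0.2654)
  expect_equal(doseRel(ref), doseRel(studyReference(study)), tolerance = 1e-9)
})

test_that("the default study replicates the exposure plan", {
  study <- defaultStudy()
  expect_length(benchmarkSets(study), 10L)
  expect_length(wedgeExposures(study), 5L)
  expect_equal(vapply(benchmarkSets(study), `[[`, numeric(1), "dose_gy"),
               seq(1, 5.5, by = 0.5))
  expect_equal(vapply(wedgeExposures(study), function(e) e@d_cax_gy,
                      numeric(1)), 1:5)
  expect_length(benchmarkSets(study)[[1]]$scans$unexposed, 5L)
})

test_that("a noiseless simulated study recovers the true parameters", {
  study <- noiselessStudy()
  bc <- benchmarkCalibration(benchmarkSets(study))
  expect_lt(abs(coefA(bc$curve) - 10) / 10, 1e-5)
  expect_lt(abs(coefB(bc$curve) - 40) / 40, 1e-5)

  # after the 16-bit disk round trip, recovery is limited only by PV
  # quantization (about 1e-5 in netOD, so about 1e-4 in the parameters)
  dir <- withr::local_tempdir()
  cfg <- noiselessConfig(seed = 13L, benchmarkRasterPx = c(32L, 32L),
                         wedgeDosesGy = c(1))
  simulateStudy(cfg, dir = dir)
  bcd <- benchmarkCalibration(benchmarkSets(loadStudy(dir)))
  expect_lt(abs(coefA(bcd$curve) - 10) / 10, 1e-3)
  expect_lt(abs(coefB(bcd$curve) - 40) / 40, 1e-3)
})

test_that("two studies with equal seeds are identical", {
  cfg <- tinyConfig(seed = 14L)
  s1 <- simulateStudy(cfg)
  s2 <- simulateStudy(cfg)
  expect_identical(pixels(wedgeExposures(s1)[[1]]@scans$exposed[[2]]),
                   pixels(wedgeExposures(s2)[[1]]@scans$exposed[[2]]))
  expect_identical(pixels(benchmarkSets(s1)[[3]]$scans$unexposed[[5]]),
                   pixels(benchmarkSets(s2)[[3]]$scans$unexposed[[5]]))
})
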