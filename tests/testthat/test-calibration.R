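truthPoints <- function(a, b, n = 2.5, x = seq(0.05, 0.5, length.out = 10)) {
  data.frame(netod = x, sigma_netod = 0, dose_gy = a * x + b * x^n)
}

test_that("the fixed-exponent fit recovers exact parameters", {
  pts <- truthPoints(10, 50)
  fit <- fitCalibration(pts, nFixed = 2.5)
  expect_lt(abs(coefA(fit) - 10) / 10, 1e-6)
  expect_lt(abs(coefB(fit) - 50) / 50, 1e-6)
  expect_identical(coefN(fit), 2.5)
  expect_equal(netODDomain(fit), range(pts$netod))

  # absent power term: recovered b compatible with zero
  fit0 <- fitCalibration(truthPoints(12, 0))
  expect_lt(abs(coefB(fit0)), 1e-8)
  expect_lte(abs(coefB(fit0)), sigmaB(fit0) + 1e-8)

  expect_error(fitCalibration(truthPoints(10, 40)[1:2, ]), class = "fitError")
  same <- data.frame(netod = rep(0.2, 5), sigma_netod = 0, dose_gy = 1:5)
  expect_error(fitCalibration(same), class = "fitError")
})

test_that("noiseless fits recover 50 random truths to relative 1e-5", {
  set.seed(31)
  for (i in 1:50) {
    a <- runif(1, 5, 15); b <- runif(1, 20, 80)
    fit <- fitCalibration(truthPoints(a, b))
    expect_lt(abs(coefA(fit) - a) / a, 1e-5)
    expect_lt(abs(coefB(fit) - b) / b, 1e-5)
  }
})

test_that("noisy fitted uncertainties give sane 3-sigma coverage", {
  set.seed(32)
  hits <- 0L
  for (i in 1:200) {
    pts <- truthPoints(10, 40)
    pts$dose_gy <- pts$dose_gy + rnorm(nrow(pts), 0, 0.02)
    fit <- fitCalibration(pts)
    if (abs(coefA(fit) - 10) <= 3 * sigmaA(fit) &&
        abs(coefB(fit) - 40) <= 3 * sigmaB(fit)) hits <- hits + 1L
  }
  expect_gte(hits / 200, 0.95)
})

test_that("doseFromNetOD evaluates and flags extrapolation", {
  cc <- CalibrationCurve(a = 10, b = 40, n = 2.5, netod_domain = c(0.1, 0.4))
  expect_equal(as.numeric(doseFromNetOD(cc, 0)), 0)
  lin <- CalibrationCurve(a = 1, b = 0 + 1e-12, n = 2.5,
                          netod_domain = c(0, 1))
  expect_equal(as.numeric(doseFromNetOD(lin, 0.5)), 0.5, tolerance = 1e-9)
  expect_equal(as.numeric(doseFromNetOD(cc, 0.3)), 10 * 0.3 + 40 * 0.3^2.5)
  expect_identical(attr(doseFromNetOD(cc, c(0.05, 0.2, 0.5)), "extrapolated"),
                   c(TRUE, FALSE, TRUE))
  expect_error(doseFromNetOD(cc, -0.1), class = "domainError")

  # strictly increasing for positive coefficients
  xs <- seq(0.001, 1, length.out = 200)
  expect_true(all(diff(as.numeric(doseFromNetOD(cc, xs))) > 0))

  # bisection inverse round-trips
  d <- as.numeric(doseFromNetOD(cc, c(0, 0.07, 0.19, 0.33)))
  expect_equal(netODFromDose(cc, d), c(0, 0.07, 0.19, 0.33), tolerance = 1e-8)
})

test_that("uncertainty components match hand arithmetic", {
  cc <- CalibrationCurve(a = 10, b = 40, n = 2.5, sigma_a = 0.2, sigma_b = 1,
                         netod_domain = c(0.05, 0.5))
  d <- 10 * 0.3 + 40 * 0.3^2.5
  expect_equal(experimentalUncertaintyPct(cc, 0.3, 0.005),
               100 * 0.005 * (10 + 100 * 0.3^1.5) / d, tolerance = 1e-12)
  expect_equal(experimentalUncertaintyPct(cc, 0.3, 0), 0)
  # b = 0 limit: reduces to sigma/netod * 100
  cb0 <- CalibrationCurve(a = 7, b = 1e-30, n = 2.5, netod_domain = c(0, 1))
  expect_equal(experimentalUncertaintyPct(cb0, 0.2, 0.004),
               0.004 / 0.2 * 100, tolerance = 1e-9)

  expect_equal(fitUncertaintyPct(cc, 0.3),
               100 * sqrt(0.09 * 0.04 + 0.3^5 * 1) / d, tolerance = 1e-12)
  czero <- CalibrationCurve(a = 10, b = 40, n = 2.5, netod_domain = c(0, 1))
  expect_equal(fitUncertaintyPct(czero, 0.3), 0)
  # sigma_b = 0, b = 0: constant relative uncertainty sigma_a / a
  cab <- CalibrationCurve(a = 8, b = 1e-30, n = 2.5, sigma_a = 0.4,
                          netod_domain = c(0, 1))
  expect_equal(fitUncertaintyPct(cab, c(0.1, 0.3)),
               rep(100 * 0.4 / 8, 2), tolerance = 1e-9)

  expect_equal(totalUncertaintyPct(3, 4), 5)
  expect_equal(totalUncertaintyPct(2.7, 0), 2.7)
  e <- experimentalUncertaintyPct(cc, 0.3, 0.005)
  f <- fitUncertaintyPct(cc, 0.3)
  expect_equal(totalUncertaintyPct(e, f), sqrt(e^2 + f^2))
  # quadrature identity on a full budget
  bud <- uncertaintyBudget(cc, c(0.1, 0.2, 0.3), c(0.004, 0.004, 0.005))
  expect_equal(bud$sigma_total_pct^2,
               bud$sigma_exp_pct^2 + bud$sigma_fit_pct^2, tolerance = 1e-12)
})

test_that("experimental uncertainty equals the finite-difference derivative", {
  cc <- CalibrationCurve(a = 10, b = 40, n = 2.5, netod_domain = c(0, 1))
  h <- 1e-7
  for (x in c(0.05, 0.12, 0.27, 0.44)) {
    sig <- 0.003
    d <- as.numeric(doseFromNetOD(cc, x))
    num <- (as.numeric(doseFromNetOD(cc, x + h)) -
            as.numeric(doseFromNetOD(cc, x - h))) / (2 * h)
    expect_equal(experimentalUncertaintyPct(cc, x, sig),
                 num * sig / d * 100, tolerance = 1e-6)
  }
})

test_that("deviation percentage follows its definition", {
  expect_equal(deviationPct(2, 2), 0)
  expect_equal(deviationPct(2, 1.9), 5)
  expect_equal(deviationPct(1, 1.03), 3)
  expect_error(deviationPct(0, 1), class = "domainError")
})

test_that("full benchmark chain doubles with a doubled truth", {
  cfgA <- noiselessConfig(seed = 61L, benchmarkRasterPx = c(32L, 32L))
  cfgB <- noiselessConfig(seed = 61L, trueA = 20, trueB = 80,
                          benchmarkRasterPx = c(32L, 32L),
                          benchmarkDosesGy = 2 * seq(1, 5.5, 0.5))
  bcA <- benchmarkCalibration(benchmarkSets(simulateStudy(cfgA)))
  bcB <- benchmarkCalibration(benchmarkSets(simulateStudy(cfgB)))
  expect_equal(coefA(bcB$curve), 2 * coefA(bcA$curve), tolerance = 1e-6)
  expect_equal(coefB(bcB$curve), 2 * coefB(bcA$curve), tolerance = 1e-6)
})
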