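test_that("TIFF round trip is bit-exact and reads the requested channel", {
  m <- matrix(sample(0:65535, 10 * 10, replace = TRUE), 10, 10)
  f <- withr::local_tempfile(fileext = ".tif")
  saveScan(ScanImage(m, dpi = 127), f)
  back <- loadScan(f, "red", dpi = 127)
  expect_identical(pixels(back), m * 1)
  expect_equal(dpi(back), 127)

  # constant red plane
  f2 <- withr::local_tempfile(fileext = ".tif")
  saveScan(constScan(30000, 10, 10), f2)
  expect_true(all(pixels(loadScan(f2)) == 30000))
})

test_that("48-bit RGB planes decode unscaled, against a byte-level fixture", {
  set.seed(3)
  r <- matrix(sample(0:65535, 6 * 5), 6, 5)
  g <- matrix(sample(0:65535, 6 * 5), 6, 5)
  b <- matrix(sample(0:65535, 6 * 5), 6, 5)
  f <- withr::local_tempfile(fileext = ".tif")
  writeRawTiff16(f, r, g, b)  # written without the tiff package
  expect_identical(pixels(loadScan(f, "red")), r * 1)
  expect_identical(pixels(loadScan(f, "green")), g * 1)
  expect_identical(pixels(loadScan(f, "blue")), b * 1)
})

test_that("8-bit scans are promoted by 257 on read", {
  m8 <- matrix(sample(0:255, 8 * 8, replace = TRUE), 8, 8)
  f <- withr::local_tempfile(fileext = ".tif")
  arr <- array(rep(m8 / 255, 3), dim = c(8, 8, 3))
  tiff::writeTIFF(arr, f, bits.per.sample = 8L, compression = "none")
  expect_identical(pixels(loadScan(f)), m8 * 257)
})

test_that("load errors are classed format errors", {
  expect_error(loadScan(tempfile()), class = "formatError")
  junk <- withr::local_tempfile(fileext = ".tif")
  writeLines("not a tiff", junk)
  expect_error(loadScan(junk), class = "formatError")
  f <- withr::local_tempfile(fileext = ".tif")
  saveScan(constScan(100), f)
  expect_error(loadScan(f, channel = "alpha"), class = "formatError")
})

test_that("reduceScanStack preserves constants and a single-scan stack", {
  sc <- constScan(12345)
  out <- reduceScanStack(rep(list(sc), 5))
  expect_lt(max(abs(pixels(out) - 12345)), 1e-8)

  # single-scan stack equals median-then-Wiener of that scan
  set.seed(5)
  noisy <- ScanImage(matrix(runif(16 * 16, 100, 200), 16, 16))
  one <- reduceScanStack(list(noisy))
  two <- reduceScanStack(list(noisy, noisy))
  expect_equal(pixels(one), pixels(two), tolerance = 1e-12)
})

test_that("reduction matches a brute-force median/mean/Wiener oracle", {
  set.seed(8)
  nr <- 12; nc <- 14
  scans <- lapply(1:5, function(i)
    ScanImage(matrix(rnorm(nr * nc, 20000, 50), nr, nc)))
  # impulse outlier in one scan
  p <- pixels(scans[[3]]); p[6, 7] <- 65000
  scans[[3]] <- ScanImage(p)

  reflect <- function(m, h) {
    ri <- c(h:1, 1:nrow(m), nrow(m):(nrow(m) - h + 1))
    ci <- c(h:1, 1:ncol(m), ncol(m):(ncol(m) - h + 1))
    m[ri, ci]
  }
  med3 <- function(m) {
    pm <- reflect(m, 1); out <- m
    for (i in 1:nrow(m)) for (j in 1:ncol(m))
      out[i, j] <- median(pm[i:(i + 2), j:(j + 2)])
    out
  }
  wien7 <- function(m) {
    pm <- reflect(m, 3)
    mu <- v <- m
    for (i in 1:nrow(m)) for (j in 1:ncol(m)) {
      win <- pm[i:(i + 6), j:(j + 6)]
      mu[i, j] <- mean(win)
      v[i, j] <- mean(win^2) - mean(win)^2
    }
    v <- pmax(v, 0)
    noise <- mean(v)
    gain <- ifelse(pmax(v, noise) > 0, pmax(v - noise, 0) / pmax(v, noise), 0)
    mu + gain * (m - mu)
  }
  expected <- wien7(Reduce(`+`, lapply(scans, function(s) med3(pixels(s)))) / 5)
  got <- pixels(reduceScanStack(scans))
  expect_equal(got, expected, tolerance = 1e-10)
  # the impulse is suppressed to within 1 PV of the clean value
  clean <- pixels(reduceScanStack(scans[-3]))
  expect_lt(abs(got[6, 7] - clean[6, 7]), 1)
})

test_that("reduceScanStack is permutation invariant and checks shapes", {
  set.seed(9)
  scans <- lapply(1:4, function(i)
    ScanImage(matrix(runif(10 * 10, 0, 1000), 10, 10)))
  a <- reduceScanStack(scans)
  b <- reduceScanStack(scans[c(3, 1, 4, 2)])
  expect_equal(pixels(a), pixels(b), tolerance = 1e-12)
  bad <- c(scans, list(ScanImage(matrix(1, 5, 5))))
  expect_error(reduceScanStack(bad), class = "dimensionError")
})

test_that("roiMean converts mm to pixels as specified", {
  # constant image: mean = constant, sd = 0, for any valid ROI
  img <- constScan(777, 20, 20)
  for (roi in list(c(1, 1), c(2, 0.5), c(3, 3))) {
    st <- roiMean(img, c(1.5, 1.5), roi)
    expect_equal(st@meanPV, 777)
    expect_equal(st@sdPV, 0)
  }
  # 127 dpi, 1 x 1 mm -> exactly 5 x 5 px
  expect_equal(roiMean(img, c(1.5, 1.5), c(1, 1))@nPx, 25L)

  # 2 x 2 px ROI over known values -> mean 25
  m <- matrix(0, 10, 10)
  m[5:6, 5:6] <- c(10, 30, 20, 40)  # column-major: rows 5,6 x cols 5,6
  img2 <- ScanImage(m, dpi = 127)
  mm <- 4 * 25.4 / 127  # pixel (5,5) in 0-based mm
  st <- roiMean(img2, c(mm, mm), c(0.4, 0.4))  # 0.4 mm -> 2 px
  # ROI anchored at the nearest pixel center extends one pixel right/down
  expect_equal(st@nPx, 4L)
  expect_equal(st@meanPV, 25)

  expect_error(roiMean(img, c(0, 0), c(10, 10)), class = "boundsError")
})
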