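# 1-D operations on netOD profiles: line averaging, gradient-based field
# segmentation, penumbra trimming, moving-mean smoothing and monotone-run
# extraction.

#' Average the central lines of a netOD map into a profile
#'
#' Denoising step before segmentation: the \code{nLines} rows (for a
#' gradient along x) or columns (gradient along y) nearest the transverse
#' center of the map are averaged into a single 1-D profile. Per-position
#' uncertainty is the transverse sample sd of the averaged lines (the
#' conservative spread convention); masked pixels are ignored.
#'
#' @param map a [NetODMap-class].
#' @param axis gradient axis: \code{"x"} (profile over columns, default) or
#'   \code{"y"}.
#' @param nLines number of central lines to average (default 25).
#' @return A [NetODProfile-class] with positions in mm from the raster
#'   corner (not yet CAX-centered).
#' @export
averageCentralLines <- function(map, axis = c("x", "y"), nLines = 25L) {
  axis <- match.arg(axis)
  m <- netOD(map)
  if (axis == "y") m <- t(m)
  nt <- nrow(m)  # transverse extent
  if (nt < nLines)
    .stopf("dimensionError",
           "map has %d transverse lines, need at least %d", nt, nLines)
  start <- (nt - nLines) %/% 2L + 1L
  block <- m[start:(start + nLines - 1L), , drop = FALSE]
  prof <- colMeans(block, na.rm = TRUE)
  sig <- if (nLines > 1L) apply(block, 2, stats::sd, na.rm = TRUE)
         else numeric(ncol(block))
  sig[!is.finite(sig)] <- 0
  NetODProfile(positions_mm = .pxPositionsMm(ncol(block), dpi(map)),
               netod = prof, sigma = sig,
               meta = list(axis = axis, n_lines = nLines))
}

#' Segment the field edges of a profile by its numerical gradient
#'
#' The left field edge is the sample of maximum gradient magnitude in the
#' left half of a lightly pre-smoothed copy of the profile, the right edge
#' the same in the right half. Each peak must exceed a noise floor of three
#' times the median absolute gradient over the outer 10 percent of samples;
#' otherwise no field is present and a segmentation error is raised. If the
#' half-maximum widths of the two edge peaks differ by more than 50 percent
#' a film-rotation warning is issued (detection only, no correction).
#'
#' @param profile a [NetODProfile-class] with at least 16 samples.
#' @param presmoothWindow moving-mean window used only for gradient
#'   localization (default 5).
#' @param noiseFloorFactor multiplier on the outer-region median absolute
#'   gradient (default 3).
#' @return list with \code{left}, \code{right} (sample indices,
#'   left < right), \code{edge_widths} (samples at half maximum) and
#'   \code{rotation_suspect} (logical).
#' @export
segmentField <- function(profile, presmoothWindow = 5L, noiseFloorFactor = 3) {
  y <- netOD(profile)
  L <- length(y)
  if (L < 16L) .stopf("dimensionError", "profile too short to segment (%d)", L)
  ys <- .movingMean(y, as.integer(presmoothWindow))
  g <- .centralGradient(ys)
  half <- L %/% 2L
  outer <- c(seq_len(max(1L, round(0.05 * L))),
             seq(L - max(1L, round(0.05 * L)) + 1L, L))
  floorv <- noiseFloorFactor * stats::median(abs(g[outer]))
  li <- which.max(abs(g[1:half]))
  ri <- half + which.max(abs(g[(half + 1L):L]))
  for (pk in c(li, ri)) {
    if (abs(g[pk]) <= floorv || abs(g[pk]) == 0)
      .stopf("segmentationError",
             "no field edge above the noise floor (peak %.3g, floor %.3g)",
             abs(g[pk]), floorv)
  }
  wl <- .peakWidth(g, li); wr <- .peakWidth(g, ri)
  rot <- max(wl, wr) / max(1, min(wl, wr)) > 1.5
  if (rot)
    warning("field edge gradient widths differ by > 50%; film rotation suspected",
            call. = FALSE)
  list(left = li, right = ri,
       left_frac = .refinePeak(abs(g), li), right_frac = .refinePeak(abs(g), ri),
       edge_widths = c(wl, wr), rotation_suspect = rot)
}

# sub-sample peak location by a parabola through the peak and its neighbors;
# used only for registration (CAX proxy), cropping stays on whole samples
.refinePeak <- function(a, pk) {
  if (pk <= 1L || pk >= length(a)) return(as.numeric(pk))
  denom <- a[pk - 1L] - 2 * a[pk] + a[pk + 1L]
  if (denom >= 0) return(as.numeric(pk))
  off <- 0.5 * (a[pk - 1L] - a[pk + 1L]) / denom
  pk + max(-0.5, min(0.5, off))
}

# samples around index pk where |g| >= half the peak magnitude (contiguous)
.peakWidth <- function(g, pk) {
  thr <- abs(g[pk]) / 2
  l <- pk; while (l > 1L && abs(g[l - 1L]) >= thr) l <- l - 1L
  r <- pk; while (r < length(g) && abs(g[r + 1L]) >= thr) r <- r + 1L
  r - l + 1L
}

# central-difference gradient with one-sided ends, per sample
.centralGradient <- function(y) {
  n <- length(y)
  g <- numeric(n)
  if (n >= 3L) g[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / 2
  g[1] <- y[2] - y[1]
  g[n] <- y[n] - y[n - 1]
  g
}

#' Check a segmented field length against the divergent beam geometry
#'
#' At depth the collimator aperture projects to
#' \code{field_size * (SSD + depth) / SSD}, so a correctly extracted profile
#' should span slightly more than the aperture. Returns a pass/fail state
#' rather than raising.
#'
#' @param edgeSpanMm distance between the detected field edges (mm).
#' @param geometry list with \code{fieldSizeCm}, \code{ssdCm},
#'   \code{depthCm}.
#' @param tolFrac relative tolerance (default 0.05).
#' @return list with \code{pass}, \code{expected_mm}, \code{span_mm}.
#' @examples
#' sanityCheckLength(157.5, list(fieldSizeCm = 15, ssdCm = 100, depthCm = 5))
#' @export
sanityCheckLength <- function(edgeSpanMm, geometry, tolFrac = 0.05) {
  expected <- geometry$fieldSizeCm * 10 *
    (geometry$ssdCm + geometry$depthCm) / geometry$ssdCm
  list(pass = abs(edgeSpanMm - expected) <= tolFrac * expected,
       expected_mm = expected, span_mm = edgeSpanMm)
}

#' Trim the penumbra remains off a segmented profile
#'
#' Keeps the samples whose 0-based index \code{i} satisfies
#' \code{floor(lo * L) <= i < floor(hi * L)} over the profile length
#' \code{L}; with the defaults this is the region from 20 to 80 percent of
#' the profile length. Positions are preserved.
#'
#' @param profile a [NetODProfile-class].
#' @param loFrac,hiFrac trim fractions, \code{0 <= lo < hi <= 1}.
#' @return the trimmed [NetODProfile-class].
#' @export
trimProfile <- function(profile, loFrac = 0.2, hiFrac = 0.8) {
  if (loFrac < 0 || hiFrac > 1 || loFrac >= hiFrac)
    .stopf("parameterError", "trim fractions must satisfy 0 <= lo < hi <= 1")
  L <- length(profile)
  keep0 <- seq.int(floor(loFrac * L), floor(hiFrac * L) - 1L)  # 0-based
  keep <- keep0 + 1L
  keep <- keep[keep >= 1L & keep <= L]
  if (length(keep) == 0L)
    .stopf("parameterError", "trimming removed every sample")
  NetODProfile(positions(profile)[keep], netOD(profile)[keep],
               netODSigma(profile)[keep], profileMeta(profile))
}

# centered moving mean with a shrinking window at the boundaries
.movingMean <- function(y, window) {
  if (window == 1L) return(y)
  n <- length(y)
  h <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, y))
  lo <- pmax(1L, seq_len(n) - h)
  hi <- pmin(n, seq_len(n) + h)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Moving-mean smoothing of a profile
#'
#' Centered moving mean with an odd window; the window shrinks symmetrically
#' at the boundaries. Positions are unchanged.
#'
#' @param profile a [NetODProfile-class].
#' @param window odd window length >= 1, at most the profile length.
#' @return the smoothed [NetODProfile-class].
#' @export
smoothProfile <- function(profile, window = 11L) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L || window > length(profile))
    .stopf("parameterError",
           "window must be odd, >= 1 and <= profile length (got %d)", window)
  NetODProfile(positions(profile),
               .movingMean(netOD(profile), window),
               netODSigma(profile), profileMeta(profile))
}

#' Extract the longest strictly monotone run of a profile
#'
#' The direction (increasing or decreasing) is chosen from the sign of the
#' overall trend (last minus first value; ties default to decreasing, the
#' wedge orientation convention). Among equally long maximal runs the one
#' containing the profile midpoint sample wins; remaining ties go to the
#' earliest run. A constant profile yields the single midpoint sample.
#'
#' @param profile a [NetODProfile-class].
#' @return the extracted [NetODProfile-class].
#' @export
extractMonotone <- function(profile) {
  y <- netOD(profile)
  n <- length(y)
  if (n == 0L) .stopf("parameterError", "empty profile")
  if (n == 1L) return(profile)
  increasing <- (y[n] - y[1]) > 0
  d <- diff(y)
  good <- if (increasing) d > 0 else d < 0
  # maximal runs of consecutive strictly monotone steps
  runs <- rle(good)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  cand <- which(runs$values)
  mid <- (n + 1L) %/% 2L
  if (length(cand) == 0L) {
    best <- c(mid, mid)
  } else {
    spans <- cbind(starts[cand], ends[cand] + 1L)  # sample indices
    lens <- spans[, 2] - spans[, 1] + 1L
    longest <- which(lens == max(lens))
    if (length(longest) > 1L) {
      inmid <- longest[spans[longest, 1] <= mid & spans[longest, 2] >= mid]
      longest <- if (length(inmid) > 0L) inmid[1] else longest[1]
    }
    best <- spans[longest[1], ]
  }
  keep <- best[1]:best[2]
  NetODProfile(positions(profile)[keep], y[keep],
               netODSigma(profile)[keep],
               c(profileMeta(profile), list(monotone_increasing = increasing)))
}
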