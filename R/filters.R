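# 2-D raster filters used by the scan-reduction chain. All filters use
# reflect padding (mirror including the edge sample) so that film edges are
# not darkened, which would bias gradient-based field segmentation.

# reflect-pad a matrix by h rows/cols on every side
.reflectPad <- function(m, h) {
  if (h == 0L) return(m)
  n <- nrow(m); p <- ncol(m)
  if (h > n || h > p) .stopf("dimensionError", "pad width exceeds raster size")
  ri <- c(h:1, 1:n, n:(n - h + 1))
  ci <- c(h:1, 1:p, p:(p - h + 1))
  m[ri, ci, drop = FALSE]
}

# k x k box mean via a summed-area table on the reflect-padded raster
.boxMean <- function(m, k) {
  if (k == 1L) return(m)
  h <- (k - 1L) %/% 2L
  pm <- .reflectPad(m, h)
  sat <- apply(pm, 2, cumsum)
  sat <- t(apply(sat, 1, cumsum))
  sat <- rbind(0, cbind(0, sat))
  n <- nrow(m); p <- ncol(m)
  i1 <- 1:n; i2 <- i1 + k - 1L
  j1 <- 1:p; j2 <- j1 + k - 1L
  (sat[i2 + 1L, j2 + 1L, drop = FALSE] - sat[i1, j2 + 1L, drop = FALSE] -
     sat[i2 + 1L, j1, drop = FALSE] + sat[i1, j1, drop = FALSE]) / (k * k)
}

# local sample sd over a k x k neighborhood (reflect padding)
.localSD <- function(m, k) {
  if (k == 1L) return(array(0, dim(m)))
  mu <- .boxMean(m, k)
  m2 <- .boxMean(m * m, k)
  n <- k * k
  v <- pmax(m2 - mu * mu, 0) * n / (n - 1)
  sqrt(v)
}

# 3 x 3 median filter via a 19-operation minimum/maximum selection network
# (vectorized over all pixels at once)
.medianFilter3 <- function(m) {
  pm <- .reflectPad(m, 1L)
  n <- nrow(m); p <- ncol(m)
  sh <- function(dr, dc) pm[(1:n) + dr, (1:p) + dc, drop = FALSE]
  q <- list(sh(0, 0), sh(0, 1), sh(0, 2),
            sh(1, 0), sh(1, 1), sh(1, 2),
            sh(2, 0), sh(2, 1), sh(2, 2))
  s <- function(i, j) {
    lo <- pmin(q[[i]], q[[j]]); hi <- pmax(q[[i]], q[[j]])
    q[[i]] <<- lo; q[[j]] <<- hi
  }
  s(2, 3); s(5, 6); s(8, 9)
  s(1, 2); s(4, 5); s(7, 8)
  s(2, 3); s(5, 6); s(8, 9)
  s(1, 4); s(6, 9); s(5, 8)
  s(4, 7); s(2, 5); s(3, 6)
  s(5, 8); s(5, 3); s(7, 5)
  s(5, 3)
  q[[5]]
}

# adaptive Wiener filter: pixel-wise local mean/variance over a k x k
# window, noise floor = mean local variance, gain = max(v - noise, 0) /
# max(v, noise). Uniform regions collapse to the local mean while
# high-variance structure (field edges, the wedge gradient) is preserved.
.wienerFilter <- function(m, k = 7L) {
  mu <- .boxMean(m, k)
  m2 <- .boxMean(m * m, k)
  v <- pmax(m2 - mu * mu, 0)
  noise <- mean(v)
  denom <- pmax(v, noise)
  gain <- ifelse(denom > 0, pmax(v - noise, 0) / denom, 0)
  mu + gain * (m - mu)
}
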