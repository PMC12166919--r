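# Shared fixtures: small scan builders, a byte-level TIFF writer that is
# independent of the tiff package (oracle for loadScan), and cached
# simulated studies reused across test files.

constScan <- function(value, nr = 16, nc = 16, dpi = 127,
                      role = "unexposed") {
  ScanImage(matrix(value, nr, nc), dpi = dpi, role = role)
}

# Minimal uncompressed little-endian RGB TIFF written byte by byte
# (header, one strip, single IFD). Serves as an independent decode oracle:
# nothing here goes through the tiff package.
writeRawTiff16 <- function(path, r, g, b) {
  stopifnot(identical(dim(r), dim(g)), identical(dim(r), dim(b)))
  h <- nrow(r); w <- ncol(r)
  u16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  u32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  entry <- function(tag, type, count, value) {
    u16(tag); u16(type); u32(count)
    if (type == 3 && count == 1) { u16(value); u16(0) } else u32(value)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("II", con, eos = NULL); u16(42L)
  nbytes <- h * w * 3L * 2L
  ifdOffset <- 8L + nbytes
  u32(ifdOffset)
  # pixel data: row-major, RGB interleaved, uint16 LE
  px <- integer(h * w * 3L)
  idx <- 1L
  for (row in seq_len(h)) for (col in seq_len(w)) {
    px[idx:(idx + 2L)] <- c(r[row, col], g[row, col], b[row, col])
    idx <- idx + 3L
  }
  writeBin(as.integer(px), con, size = 2, endian = "little")
  nEntries <- 10L
  bpsOffset <- ifdOffset + 2L + nEntries * 12L + 4L
  u16(nEntries)
  entry(256L, 3L, 1L, w)          # ImageWidth
  entry(257L, 3L, 1L, h)          # ImageLength
  entry(258L, 3L, 3L, bpsOffset)  # BitsPerSample -> offset
  entry(259L, 3L, 1L, 1L)         # Compression: none
  entry(262L, 3L, 1L, 2L)         # Photometric: RGB
  entry(273L, 4L, 1L, 8L)         # StripOffsets
  entry(277L, 3L, 1L, 3L)         # SamplesPerPixel
  entry(278L, 3L, 1L, h)          # RowsPerStrip
  entry(279L, 4L, 1L, nbytes)     # StripByteCounts
  entry(284L, 3L, 1L, 1L)         # PlanarConfig: chunky
  u32(0L)                         # no next IFD
  u16(c(16L, 16L, 16L))           # BitsPerSample values
  invisible(path)
}

# cached studies (simulation is seeded, so caching is deterministic)
.studyCache <- new.env(parent = emptyenv())

cachedStudy <- function(key, make) {
  if (is.null(.studyCache[[key]])) .studyCache[[key]] <- make()
  .studyCache[[key]]
}

noiselessConfig <- function(seed = 7L, ...)
  groundTruthConfig(seed = seed, pixelNoiseRel = 0,
                    filmNonuniformityRel = 0, ...)

noiselessStudy <- function()
  cachedStudy("noiseless", function() simulateStudy(noiselessConfig()))

defaultStudy <- function()
  cachedStudy("default", function() simulateStudy(groundTruthConfig(seed = 42L)))

# a small, quick-to-simulate configuration (short strips, tiny field) used
# where only plumbing is under test, not the study conditions
tinyConfig <- function(seed = 11L, ...)
  groundTruthConfig(seed = seed, fieldSizeCm = 4, marginMm = 10,
                    wedgeRasterRowsPx = 40L, benchmarkRasterPx = c(32L, 32L),
                    benchmarkDosesGy = c(1, 2, 3, 4), wedgeDosesGy = c(2),
                    ...)
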