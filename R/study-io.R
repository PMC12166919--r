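# On-disk layout of a simulated (or measured) study:
#   manifest.json                    full GroundTruthConfig
#   reference.csv / reference.yaml   wedge profile + attenuation/geometry
#   benchmark_XX/{unexposed,exposed,background}_Y.tif
#   wedge_XX/{unexposed,exposed,background}_Y.tif

.cfgToList <- function(cfg) {
  list(true_a = cfg@true_a, true_b = cfg@true_b, true_n = cfg@true_n,
       pv_unexp_mean = cfg@pv_unexp_mean, pv_bckg_mean = cfg@pv_bckg_mean,
       pixel_noise_rel = cfg@pixel_noise_rel,
       film_nonuniformity_rel = cfg@film_nonuniformity_rel,
       nonuniformity_corr_mm = cfg@nonuniformity_corr_mm,
       n_repeat_scans = cfg@n_repeat_scans, dpi = cfg@dpi, seed = cfg@seed,
       geometry = cfg@geometry, penumbra_mm = cfg@penumbra_mm,
       wedge_dynamic_range = cfg@wedge_dynamic_range,
       scatter_floor = cfg@scatter_floor,
       benchmark_doses_gy = cfg@benchmark_doses_gy,
       wedge_doses_gy = cfg@wedge_doses_gy,
       benchmark_raster_px = cfg@benchmark_raster_px,
       wedge_raster_rows_px = cfg@wedge_raster_rows_px,
       margin_mm = cfg@margin_mm, output_gy_per_mu = cfg@output_gy_per_mu)
}

.cfgFromList <- function(l) {
  g <- l$geometry
  groundTruthConfig(
    trueA = l$true_a, trueB = l$true_b, trueN = l$true_n,
    pvUnexpMean = l$pv_unexp_mean, pvBckgMean = l$pv_bckg_mean,
    pixelNoiseRel = l$pixel_noise_rel,
    filmNonuniformityRel = l$film_nonuniformity_rel,
    nonuniformityCorrMm = l$nonuniformity_corr_mm,
    nRepeatScans = l$n_repeat_scans, dpi = l$dpi, seed = l$seed,
    fieldSizeCm = g$fieldSizeCm, ssdCm = g$ssdCm, depthCm = g$depthCm,
    wedgeAngleDeg = g$wedgeAngleDeg, attenuationCax = g$attenuationCax,
    penumbraMm = l$penumbra_mm, wedgeDynamicRange = l$wedge_dynamic_range,
    scatterFloor = l$scatter_floor,
    benchmarkDosesGy = as.numeric(l$benchmark_doses_gy),
    wedgeDosesGy = as.numeric(l$wedge_doses_gy),
    benchmarkRasterPx = as.integer(l$benchmark_raster_px),
    wedgeRasterRowsPx = l$wedge_raster_rows_px,
    marginMm = l$margin_mm, outputGyPerMu = l$output_gy_per_mu)
}

#' Write / read the wedge reference as CSV + YAML sidecar
#'
#' The CSV holds \code{position_mm, dose_rel}; the YAML sidecar (same path
#' with extension \code{.yaml}) holds \code{attenuation_cax} and the
#' geometry.
#'
#' @param ref a [WedgeReference-class].
#' @param csvPath path of the CSV file.
#' @return \code{writeWedgeReference}: the path, invisibly;
#'   \code{readWedgeReference}: a [WedgeReference-class].
#' @export
writeWedgeReference <- function(ref, csvPath) {
  utils::write.csv(data.frame(position_mm = positions(ref),
                              dose_rel = doseRel(ref)),
                   csvPath, row.names = FALSE)
  yaml::write_yaml(list(attenuation_cax = attenuationCAX(ref),
                        geometry = geometry(ref)),
                   sub("\\.csv$", ".yaml", csvPath))
  invisible(csvPath)
}

#' @rdname writeWedgeReference
#' @export
readWedgeReference <- function(csvPath) {
  df <- utils::read.csv(csvPath)
  side <- yaml::read_yaml(sub("\\.csv$", ".yaml", csvPath))
  WedgeReference(df$position_mm, df$dose_rel,
                 attenuation_cax = side$attenuation_cax,
                 geometry = side$geometry)
}

.writeStack <- function(stack, dir, prefix) {
  for (i in seq_along(stack))
    saveScan(stack[[i]], file.path(dir, sprintf("%s_%d.tif", prefix, i)))
}

.readStack <- function(dir, prefix, role, dpi) {
  files <- list.files(dir, pattern = sprintf("^%s_\\d+\\.tif$", prefix),
                      full.names = TRUE)
  files <- files[order(as.integer(sub(".*_(\\d+)\\.tif$", "\\1", files)))]
  lapply(files, loadScan, channel = "red", role = role, dpi = dpi)
}

#' Write a FilmStudy to disk
#'
#' @param study a [FilmStudy-class].
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
writeStudy <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) .stopf("ioError", "cannot create directory %s", dir)
  cfg <- studyConfig(study)
  jsonlite::write_json(.cfgToList(cfg), file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  writeWedgeReference(studyReference(study), file.path(dir, "reference.csv"))
  bsets <- benchmarkSets(study)
  for (i in seq_along(bsets)) {
    d <- file.path(dir, sprintf("benchmark_%02d", i))
    dir.create(d, showWarnings = FALSE)
    for (role in c("unexposed", "exposed", "background"))
      .writeStack(bsets[[i]]$scans[[role]], d, role)
  }
  wexp <- wedgeExposures(study)
  for (i in seq_along(wexp)) {
    d <- file.path(dir, sprintf("wedge_%02d", i))
    dir.create(d, showWarnings = FALSE)
    for (role in c("unexposed", "exposed", "background"))
      .writeStack(wexp[[i]]@scans[[role]], d, role)
  }
  invisible(dir)
}

#' Load a FilmStudy from disk
#'
#' Reads the manifest, the wedge reference and every scan triplet written by
#' [writeStudy()] (or [simulateStudy()] with a directory).
#'
#' @param dir study directory.
#' @return A [FilmStudy-class].
#' @export
loadStudy <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) .stopf("ioError", "no manifest.json in %s", dir)
  cfg <- .cfgFromList(jsonlite::read_json(mpath, simplifyVector = TRUE))
  ref <- readWedgeReference(file.path(dir, "reference.csv"))
  readTriplet <- function(d) {
    lapply(stats::setNames(nm = c("unexposed", "exposed", "background")),
           function(role) .readStack(d, role, role, cfg@dpi))
  }
  benchmark <- lapply(seq_along(cfg@benchmark_doses_gy), function(i) {
    d <- file.path(dir, sprintf("benchmark_%02d", i))
    if (!dir.exists(d)) .stopf("ioError", "missing benchmark set %s", d)
    list(scans = readTriplet(d), dose_gy = cfg@benchmark_doses_gy[i])
  })
  wedge <- lapply(seq_along(cfg@wedge_doses_gy), function(i) {
    d <- file.path(dir, sprintf("wedge_%02d", i))
    if (!dir.exists(d)) .stopf("ioError", "missing wedge set %s", d)
    WedgeExposure(readTriplet(d), d_cax_gy = cfg@wedge_doses_gy[i], axis = "x")
  })
  new("FilmStudy", benchmark = benchmark, wedge = wedge, reference = ref,
      config = cfg)
}
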