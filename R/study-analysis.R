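# High-level study analysis used by the validation suite and the
# reproduction script: runs the complete benchmark and wedge pipelines on a
# simulated study and summarizes curve-vs-curve deviations, the uncertainty
# budget and the dose-profile self-similarity check.

#' Analyze one simulated film-calibration study
#'
#' Simulates a study from \code{cfg} (in memory), fits the benchmark curve,
#' extracts every wedge gradient once, then fits each single-gradient curve
#' and the concatenated all-gradient curve. Deviations are evaluated with
#' the percent-deviation statistic at the benchmark measurement netODs,
#' against the benchmark fitted curve; \code{dev_in} restricts to benchmark
#' points inside each wedge curve's fitted netOD domain, \code{dev_all}
#' evaluates all benchmark points (extrapolation allowed).
#'
#' @param cfg a [GroundTruthConfig-class].
#' @return list with \code{bc} (benchmark fit), \code{curves} (per-gradient
#'   wedge curves), \code{concat_curve}, and the summary scalars
#'   \code{dev_in} / \code{dev_all} (named per CAX dose, percent),
#'   \code{dev_concat} (percent), \code{budget_max_above_1gy} (percent, max
#'   total uncertainty at nominal doses > 1 Gy) and \code{selfsim_max_pct}
#'   (percent, max point-wise disagreement between the scaled reference
#'   profile and the film profile pushed through the benchmark curve, for
#'   the lowest-dose wedge exposure).
#' @export
analyzeStudyReplicate <- function(cfg) {
  study <- simulateStudy(cfg)
  ref <- studyReference(study)
  bc <- benchmarkCalibration(benchmarkSets(study))
  bcPts <- data.frame(
    netod = bc$points$netod,
    dose_gy = as.numeric(doseFromNetOD(bc$curve, bc$points$netod)))

  wexp <- wedgeExposures(study)
  profiles <- lapply(wexp, extractWedgeProfile, geometry = geometry(ref))

  singles <- lapply(seq_along(wexp), function(i)
    wedgeCalibration(wexp[i], ref, profiles = profiles[i]))
  devIn <- devAll <- numeric(length(wexp))
  for (i in seq_along(wexp)) {
    cmp <- compareToBenchmark(singles[[i]]$curve, bcPts)
    devAll[i] <- max(cmp$deviation_pct)
    inDom <- !cmp$extrapolated
    devIn[i] <- if (any(inDom)) max(cmp$deviation_pct[inDom]) else NA_real_
  }
  names(devIn) <- names(devAll) <-
    sprintf("dcax_%g", vapply(wexp, function(e) e@d_cax_gy, numeric(1)))

  concat <- wedgeCalibration(wexp, ref, profiles = profiles)
  devConcat <- max(compareToBenchmark(concat$curve, bcPts)$deviation_pct)

  above1 <- bc$points$dose_gy > 1
  budgetMax <- max(bc$budget$sigma_total_pct[above1])

  # self-similarity: scaled reference vs film netOD profile through the
  # benchmark curve, on the trimmed region of the lowest-dose exposure
  i1 <- which.min(vapply(wexp, function(e) e@d_cax_gy, numeric(1)))
  p1 <- profiles[[i1]]
  est <- estimateDoseProfile(ref, wexp[[i1]]@d_cax_gy, positions(p1))$dose_gy
  film <- as.numeric(doseFromNetOD(bc$curve, netOD(p1)))
  selfsim <- max(abs(est - film) / est) * 100

  list(bc = bc, curves = lapply(singles, `[[`, "curve"),
       concat_curve = concat$curve,
       dev_in = devIn, dev_all = devAll, dev_concat = devConcat,
       budget_max_above_1gy = budgetMax, selfsim_max_pct = selfsim)
}

#' Replicate the study analysis over independent seeds
#'
#' Runs [analyzeStudyReplicate()] for \code{n} seeds \code{baseSeed + 1,
#' ..., baseSeed + n} with otherwise default study conditions and collects
#' the per-replicate summary scalars.
#'
#' @param baseSeed integer base seed.
#' @param n number of replicates.
#' @param ... further arguments passed to [groundTruthConfig()].
#' @return list with matrices \code{dev_in}, \code{dev_all} (replicates x
#'   gradients) and vectors \code{dev_concat}, \code{budget_max_above_1gy},
#'   \code{selfsim_max_pct}.
#' @export
replicateStudyAnalysis <- function(baseSeed = 1234L, n = 20L, ...) {
  reps <- lapply(seq_len(n), function(i) {
    cfg <- groundTruthConfig(seed = as.integer(baseSeed) + i, ...)
    analyzeStudyReplicate(cfg)
  })
  list(dev_in = do.call(rbind, lapply(reps, `[[`, "dev_in")),
       dev_all = do.call(rbind, lapply(reps, `[[`, "dev_all")),
       dev_concat = vapply(reps, `[[`, numeric(1), "dev_concat"),
       budget_max_above_1gy = vapply(reps, `[[`, numeric(1),
                                     "budget_max_above_1gy"),
       selfsim_max_pct = vapply(reps, `[[`, numeric(1), "selfsim_max_pct"))
}
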