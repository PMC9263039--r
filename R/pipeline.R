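## End-to-end orchestration: simulate -> render -> reconstruct ->
## morphometry -> dry-mass analytics, with per-FOV error containment and a
## two-"laboratory" replication mode.

#' Run the full simulated DHM cytotoxicity assay
#'
#' Simulates the population of every experiment/condition/FOV, renders the
#' 7-frame hologram series at the requested time points, reconstructs
#' averaged compensated phase images, and computes the three readouts per
#' condition: temporal dry-mass development, 12-h dry-mass increment
#' (mean +- sd over FOVs, with significance stars versus the medium
#' control), and the fraction of rounded cells at the endpoint.
#'
#' Reconstruction cost scales with the number of time points x FOVs x 7
#' frames; `reconstructTimepointsH` restricts imaging to a subset of the
#' recorded time points (the population dynamics always run at full
#' resolution).  Errors in a single FOV are logged and skipped; the
#' remaining FOVs complete.
#'
#' @param config an [AssayConfig-class].
#' @param reconstructTimepointsH time points (h) to image; default all
#'   recorded ones.  Must include 0 and the endpoint.
#' @param refocus "off", "auto", or a numeric distance (um) applied to every
#'   reconstruction.
#' @param verbose print per-FOV progress.
#' @return an [AssayResult-class].
#' @export
runAssay <- function(config, reconstructTimepointsH = NULL, refocus = "off",
                     verbose = FALSE) {
  validObject(config)
  pop <- config@population; opt <- config@optics
  sim <- simulatePopulation(pop, opt, config@seed)
  tps <- if (is.null(reconstructTimepointsH)) pop@timepoints
  else sort(unique(reconstructTimepointsH))
  if (!all(tps %in% pop@timepoints))
    stop("reconstructTimepointsH must be recorded time points")
  endT <- max(pop@timepoints)
  if (!all(c(0, endT) %in% tps))
    stop("imaging must include t = 0 and the endpoint")
  conds <- pop@conditions
  carrier <- carrierFrequency(opt)

  series <- list(); summaries <- list(); regionsAll <- list()
  logrec <- list()
  truthFov <- fovTable(sim)
  for (e in seq_len(pop@nExperiments)) {
    for (k in seq_len(nrow(conds))) {
      for (v in seq_len(pop@nFOV)) {
        lab <- conds$label[k]
        tag <- sprintf("e%d_%s_f%d", e, lab, v)
        res <- tryCatch({
          dm <- numeric(length(tps))
          endSeg <- NULL
          for (ti in seq_along(tps)) {
            t <- tps[ti]
            phi <- truthPhase(sim, e, lab, v, t, config@drymass)
            holos <- renderHologramSeries(
              phi, opt, seed = .subSeed(config@seed, e, k, v, t, 911L),
              meta = list(experiment = e, condition = lab, fov = v,
                          timeH = t))
            qpi <- reconstructSeries(holos, carrier = carrier,
                                     refocus = refocus)
            dm[ti] <- dryMass(qpi, config@drymass)
            if (t == endT)
              endSeg <- segmentCells(qpi, config@segmentation,
                                     config@drymass)
          }
          tf <- truthFov[truthFov$experiment == e &
                           truthFov$condition == lab &
                           truthFov$fov == v, ]
          trueDmi <- tf$truePopulationDryMassPg[tf$timeH == endT] -
            tf$truePopulationDryMassPg[tf$timeH == 0]
          rf <- roundedFraction(endSeg$regions, config@segmentation@cRound)
          list(
            series = data.frame(
              experiment = e, condition = lab,
              concentration = conds$concentration[k], fov = v, timeH = tps,
              dmPg = dm, dmRelPg = relativeDM(tps, dm)),
            summary = data.frame(
              experiment = e, condition = lab,
              concentration = conds$concentration[k], fov = v,
              dmiPg = dryMassIncrement(tps, dm, endT),
              trueDmiPg = trueDmi,
              nRounded = rf$nRounded, nTotal = rf$nTotal,
              roundedFraction = rf$fraction),
            regions = if (nrow(endSeg$regions))
              cbind(data.frame(experiment = e, condition = lab, fov = v),
                    endSeg$regions)
            else NULL)
        }, error = function(err) err)
        if (inherits(res, "error")) {
          logrec[[length(logrec) + 1L]] <- data.frame(
            fovTag = tag, level = "error", message = conditionMessage(res))
        } else {
          series[[tag]] <- res$series
          summaries[[tag]] <- res$summary
          if (!is.null(res$regions)) regionsAll[[tag]] <- res$regions
          if (verbose) message("done ", tag)
        }
      }
    }
  }
  fovSeries <- do.call(rbind, series)
  fovSummary <- do.call(rbind, summaries)
  rownames(fovSeries) <- rownames(fovSummary) <- NULL
  agg <- aggregateConditions(fovSummary)
  sig <- significanceVsControl(fovSummary)
  agg$pValue <- sig$pValue[match(agg$condition, sig$condition)]
  agg$stars <- sig$stars[match(agg$condition, sig$condition)]
  regions <- if (length(regionsAll)) do.call(rbind, regionsAll)
  else .emptyRegions()
  rownames(regions) <- NULL
  new("AssayResult", fovSeries = fovSeries, fovSummary = fovSummary,
      conditionSummary = agg, regions = regions, truth = sim@truth,
      config = config,
      log = if (length(logrec)) do.call(rbind, logrec)
      else data.frame(fovTag = character(), level = character(),
                      message = character()))
}

#' Derive a "laboratory variant" configuration
#'
#' Emulates a second laboratory by perturbing the configuration with the
#' factors in `config@labVariants`: initial cell count, growth rate, and
#' noise amplitudes.  The seed is offset per variant so the two laboratories
#' draw independent populations.
#'
#' @param config an [AssayConfig-class] with a non-empty `labVariants`.
#' @param label variant label.
#' @return a perturbed [AssayConfig-class].
#' @export
labVariantConfig <- function(config, label) {
  lv <- config@labVariants
  i <- match(label, lv$label)
  if (is.na(i)) stop("unknown lab variant: ", label)
  pop <- config@population
  opt <- config@optics
  pop@initialCellCount <-
    as.integer(round(pop@initialCellCount * lv$cellCountFactor[i]))
  pop@growthRate <- pop@growthRate * lv$growthFactor[i]
  opt@shotNoiseScale <- opt@shotNoiseScale * lv$noiseFactor[i]
  opt@parasiticFringeAmplitude <-
    opt@parasiticFringeAmplitude * lv$noiseFactor[i]
  config@population <- pop
  config@optics <- opt
  config@seed <- .subSeed(config@seed, 7919L, i)
  config
}

#' Compare two assay results condition by condition
#'
#' Per-condition differences in mean dry-mass increment and pooled rounded
#' fraction between two runs (e.g. two emulated laboratories).  Comparing a
#' result with itself yields exact zeros.
#'
#' @param resultA,resultB [AssayResult-class] objects over identical
#'   condition grids.
#' @return data.frame: condition, concentration, dmiMeanPgA/B, dmiDiffPg,
#'   roundedFractionA/B, roundedFractionDiff.
#' @export
interlabCompare <- function(resultA, resultB) {
  a <- resultA@conditionSummary; b <- resultB@conditionSummary
  if (!identical(sort(a$condition), sort(b$condition)))
    stop("condition grids differ")
  b <- b[match(a$condition, b$condition), ]
  data.frame(
    condition = a$condition, concentration = a$concentration,
    dmiMeanPgA = a$dmiMeanPg, dmiMeanPgB = b$dmiMeanPg,
    dmiDiffPg = a$dmiMeanPg - b$dmiMeanPg,
    roundedFractionA = a$roundedFraction, roundedFractionB = b$roundedFraction,
    roundedFractionDiff = a$roundedFraction - b$roundedFraction)
}

#' Write an assay result to disk
#'
#' Tidy CSV tables (per FOV x time, per FOV, per condition, per region) and
#' a JSON run report with the configuration hash and seed.  Output bytes are
#' fully determined by the result object.
#'
#' @param result an [AssayResult-class].
#' @param dir output directory (created if missing).
#' @return invisibly, the vector of written paths.
#' @export
writeAssayResult <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("fov_series.csv", "fov_summary.csv",
                            "condition_summary.csv", "regions.csv",
                            "run_report.json"))
  write.csv(result@fovSeries, paths[1], row.names = FALSE)
  write.csv(result@fovSummary, paths[2], row.names = FALSE)
  write.csv(result@conditionSummary, paths[3], row.names = FALSE)
  write.csv(result@regions, paths[4], row.names = FALSE)
  tmp <- tempfile()
  saveRDS(result@config, tmp, version = 2)
  hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  jsonlite::write_json(
    list(configHash = hash, seed = result@config@seed,
         package = as.character(utils::packageVersion("holoassay")),
         nFOVCompleted = nrow(result@fovSummary),
         nErrors = sum(result@log$level == "error"),
         warnings = result@log$message),
    paths[5], auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}
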