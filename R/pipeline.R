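# End-to-end pipeline orchestration on synthetic data.

#' Default pipeline configuration
#'
#' Every stated analysis setting appears here exactly once: 7 FIR timepoints
#' with contrasts over timepoints 3-4, 10 AR lags, 6 discarded lead-in
#' volumes per run, voxelwise two-tailed p < 0.01, 10,000 pattern iterations
#' with similarity cutoffs 0.3 / 0.7, TR 2 s, four 330-s runs with the
#' 84/80/20/20 trial mix and 30/40/30 ITIs. Simulation sizes (grid, calibration
#' iterations) are desk-scale defaults and freely adjustable.
#'
#' @param seed Master seed; stage seeds are derived from it.
#' @return Nested list of class `pipeline_config`.
#' @export
defaultConfig <- function(seed = 1L) {
  structure(list(
    seed = seed,
    design = list(
      counts = c("neutral-go" = 84, "aversive-go" = 80,
                 "neutral-nogo" = 20, "aversive-nogo" = 20),
      nRuns = 4, runDuration = 330, trialDuration = 2,
      itiProportions = c("2" = 0.3, "4" = 0.4, "6" = 0.3)),
    cohort = list(n = 21, nHigh = 10, targetCorr = 0.78),
    grid = list(dim = c(20, 20, 12), voxelSize = 3, nRegions = 26),
    effects = list(amplitudes = 0.5, arbsSlopes = 0, bisSlopes = 0),
    noise = list(ar = c(0.3, 0.1), sd = 1, fwhmMm = 6,
                 driftAmp = 0.5, motionAmp = 0.2),
    glm = list(tr = 2, nFir = 7, contrastTimepoints = c(3, 4),
               maxLag = 10, discardVolumes = 6, combine = "mean"),
    threshold = list(voxelP = 0.01, connectivity = "faces",
                     calibration = "montecarlo", calibrationIterations = 200,
                     alpha = 0.05),
    pattern = list(iterations = 10000, cutoffs = c(0.3, 0.7)),
    behavior = list(testIterations = 10000)
  ), class = "pipeline_config")
}

# Plain-text checksum of a config (stable across sessions; no external
# digest dependency).
configHash <- function(config) {
  s <- utf8ToInt(paste(deparse(unclass(config)), collapse = ""))
  sprintf("%08x", sum(s * (seq_along(s) %% 251)) %% .Machine$integer.max)
}

#' Run the full synthetic-data analysis pipeline
#'
#' Executes the stages in order: cohort + atlas + session designs ->
#' synthetic BOLD generation -> first-level FIR GLM with pre-whitening and
#' three contrasts per participant -> nine second-level maps ->
#' cluster-extent calibration (Monte Carlo by default) and thresholding ->
#' cluster report with timecourse QA -> correlation-pattern analysis with the
#' stratified split test -> behavioral statistics. All randomness derives
#' from `config$seed`.
#'
#' @param config A `pipeline_config` (see [defaultConfig()]).
#' @param outDir Optional directory; if given, products are written there
#'   (TSV/JSON) together with the run manifest.
#' @return List with `statMaps`, `clusterReports`, `qa`, `similarity`,
#'   `patterns`, `behavior`, `cohort`, `extent`, `smoothness`, `manifest`.
#' @export
runPipeline <- function(config = defaultConfig(), outDir = NULL) {
  t0 <- Sys.time()
  stage <- function(name, expr) {
    tryCatch(force(expr),
             error = function(e) stop("stage '", name, "': ", conditionMessage(e),
                                      call. = FALSE))
  }
  cohort <- stage("cohort", generateCohort(
    n = config$cohort$n, nHigh = config$cohort$nHigh,
    targetCorr = config$cohort$targetCorr, seed = childSeed(config$seed, 1)))
  atlas <- stage("atlas", generateAtlasFixture(
    dim = config$grid$dim, nRegions = config$grid$nRegions,
    voxelSize = config$grid$voxelSize, seed = childSeed(config$seed, 2)))
  design <- stage("design", generateSessionDesign(
    counts = config$design$counts, nRuns = config$design$nRuns,
    runDuration = config$design$runDuration,
    trialDuration = config$design$trialDuration,
    itiProportions = config$design$itiProportions,
    seed = childSeed(config$seed, 3)))
  eff <- effectSpec(config$grid$nRegions,
                    amplitudes = config$effects$amplitudes,
                    arbsSlopes = config$effects$arbsSlopes,
                    bisSlopes = config$effects$bisSlopes)
  ns <- noiseSpec(ar = config$noise$ar, sd = config$noise$sd,
                  fwhmMm = config$noise$fwhmMm, driftAmp = config$noise$driftAmp,
                  motionAmp = config$noise$motionAmp)
  cds <- contrastDefs(timepoints = config$glm$contrastTimepoints,
                      combine = config$glm$combine)

  firstLevel <- vector("list", nrow(cohort))
  residSample <- NULL
  for (i in seq_len(nrow(cohort))) {
    ses <- stage(paste0("synthesis:", cohort$id[i]), generateBoldSession(
      cohort[i, ], design, eff, ns, atlas, seed = childSeed(config$seed, 100 + i),
      tr = config$glm$tr, leadInVolumes = config$glm$discardVolumes))
    fit <- stage(paste0("first-level:", cohort$id[i]),
                 fitFirstLevel(ses, maxLag = config$glm$maxLag))
    firstLevel[[i]] <- lapply(cds, function(cd) computeContrast(fit, cd))
    if (i == 1) {
      residSample <- array(0, c(fit$dims, 4))
      for (k in 1:4)
        residSample[, , , k] <- toVolume(fit$residuals[k * 30, ], fit$voxels, fit$dims)
      maskRef <- ses$mask
      sessionsKeep <- list(ses)   # retained for QA timecourses
    } else if (i <= 3) sessionsKeep[[i]] <- ses
  }

  statMaps <- stage("group", fitGroupMaps(firstLevel, cohort))
  smoothness <- stage("smoothness",
                      estimateSmoothness(residSample, maskRef,
                                         config$grid$voxelSize))
  extent <- stage("calibration", montecarloClusterThreshold(
    maskRef, fwhmMm = max(smoothness$fwhmCombinedMm, config$grid$voxelSize),
    voxelSize = config$grid$voxelSize, voxelP = config$threshold$voxelP,
    alpha = config$threshold$alpha,
    nIter = config$threshold$calibrationIterations,
    connectivity = config$threshold$connectivity,
    seed = childSeed(config$seed, 4)))

  clusterReports <- list(); qa <- list()
  for (cn in names(statMaps$maps))
    for (mn in names(statMaps$maps[[cn]])) {
      m <- statMaps$maps[[cn]][[mn]]
      rep <- clusterReport(m$t, m$df, statMaps$voxels, statMaps$dims,
                           voxelP = config$threshold$voxelP,
                           extent = extent$extent,
                           voxelSize = config$grid$voxelSize,
                           connectivity = config$threshold$connectivity)
      key <- paste(cn, mn, sep = ":")
      clusterReports[[key]] <- rep
      if (nrow(rep)) {
        t3d <- toVolume(m$t, statMaps$voxels, statMaps$dims)
        th <- thresholdVoxelwise(m$t, config$threshold$voxelP, m$df)
        keep3d <- toVolume(th$keep, statMaps$voxels, statMaps$dims, fill = FALSE)
        cl <- findClusters(keep3d, config$threshold$connectivity)
        big <- which(cl$sizes >= extent$extent)
        qa[[key]] <- lapply(big, function(k)
          qaClusterTimecourses(cl$voxels[[k]], sessionsKeep))
      }
    }

  values <- stage("pattern", regionContrastValues(firstLevel, atlas))
  patterns <- list(
    ARBS = computePattern(values, cohort$arbs, "ARBS"),
    BIS = computePattern(values, cohort$bis, "BIS"))
  similarity <- stage("split-test", splitSimilarityTest(
    values, cohort$arbs, cohort$bis, cohort$risk_class,
    nIter = config$pattern$iterations, cutoffs = config$pattern$cutoffs,
    seed = childSeed(config$seed, 5)))

  behavior <- stage("behavior", {
    bh <- generateBehavior(cohort, seed = childSeed(config$seed, 6))
    nIt <- config$behavior$testIterations
    list(table = bh,
         commissionVsZero = bootstrapMeanTest(bh$commission_pct, nIt,
                                              seed = childSeed(config$seed, 7)),
         aversiveVsNeutral = permutationPairedTest(
           bh$commission_aversive_pct, bh$commission_neutral_pct, nIt,
           seed = childSeed(config$seed, 8)),
         commissionVsArbs = bootstrapRegression(bh$commission_pct, cohort$arbs,
                                                nIt, seed = childSeed(config$seed, 9)),
         commissionVsBis = bootstrapRegression(bh$commission_pct, cohort$bis,
                                               nIt, seed = childSeed(config$seed, 10)),
         latency = latencyPairedTest(bh$latency_neutral_ms, bh$latency_aversive_ms))
  })

  manifest <- list(package = "emogonogo",
                   version = as.character(utils::packageVersion("emogonogo")),
                   configHash = configHash(config), seed = config$seed,
                   started = format(t0), elapsed_s = as.numeric(Sys.time() - t0,
                                                                units = "secs"))
  out <- list(statMaps = statMaps, clusterReports = clusterReports, qa = qa,
              similarity = similarity, patterns = patterns, values = values,
              behavior = behavior, cohort = cohort, extent = extent,
              smoothness = smoothness, manifest = manifest)
  if (!is.null(outDir)) writePipelineProducts(out, outDir, config)
  out
}

# Serialize the pipeline products as TSV/JSON with the manifest alongside.
writePipelineProducts <- function(out, outDir, config) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  writeCohort(out$cohort, file.path(outDir, "cohort.tsv"))
  for (key in names(out$clusterReports))
    utils::write.table(out$clusterReports[[key]],
                       file.path(outDir, paste0("clusters_", gsub(":", "_", key), ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(similarity = out$similarity[c("meanS", "sdS", "propBelow", "propAbove",
                                       "nIter", "cutoffs")],
         extent = out$extent[c("extent", "alpha", "voxelP", "fwhmMm")],
         smoothness = list(fwhmMm = out$smoothness$fwhmMm,
                           combined = out$smoothness$fwhmCombinedMm),
         manifest = out$manifest),
    file.path(outDir, "results.json"), auto_unbox = TRUE, digits = NA)
  utils::write.table(
    data.frame(column = colnames(out$values),
               ARBS = as.numeric(out$patterns$ARBS),
               BIS = as.numeric(out$patterns$BIS)),
    file.path(outDir, "correlation_patterns.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(outDir)
}
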