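## End-to-end orchestration of the two analysis pipelines
## (stimulus-locked and response-locked) over the package's stages.

writeTsv <- function(df, path, cfg) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# veplink config_hash=%s seed=%s", cfg$configHash,
                     cfg$seed), con)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}

readTsv <- function(path) read.delim(path, comment.char = "#",
                                     stringsAsFactors = FALSE)

#' Run the analysis pipeline
#'
#' Executes the configured stages in order on seeded synthetic data:
#'
#' * `simulate`: montage, per-subject behavioral sessions and epoched EEG
#'   (written as containers under `outDir/epochs/`).
#' * `stimuli`: a batch of Gaborized displays with density checks
#'   (element tables under `outDir/stimuli/`).
#' * `behavior`: per-subject probit fits, the d-prime/log-jitter
#'   regressions and the inverse-function jitter calibration.
#' * `neurometric`: preprocessing, slope maps, spatiotemporal cluster
#'   permutation and the behavioral-CI match mask, both stimulus-locked
#'   and response-locked.
#' * `components`: peak table and the multilevel LRT model per component.
#' * `decode`: per-subject shrinkage-LDA timecourses and the temporal
#'   cluster test on accuracies.
#' * `report`: summary tables (and figures when `figures = TRUE` and a
#'   PNG device is available).
#'
#' Every table written carries the config hash and seed; identical
#' config + seed reruns produce identical outputs.
#'
#' @param config a config list (see [demoRunConfig()]) or path to a YAML
#'   file ([readRunConfig()]).
#' @param stages subset of stages to run (default: `config$stages`).
#' @return invisibly, a list with the in-memory stage products
#'   (`montage`, `behavior`, `behaviorTables`, `slopeMap`, `clusters`,
#'   `mask`, `responseClusters`, `responseMask`, `peaks`,
#'   `componentModel`, `decoding`, `accuracyClusters`, `truth`, `outDir`).
#' @export
runPipeline <- function(config = demoRunConfig(), stages = NULL) {
  if (is.character(config)) config <- readRunConfig(config)
  else config <- finalizeRunConfig(config)
  stages <- stages %||% config$stages
  known <- c("simulate", "stimuli", "behavior", "neurometric",
             "components", "decode", "report")
  stopIf(!all(stages %in% known), "unknown stage(s): ",
         paste(setdiff(stages, known), collapse = ", "))
  out <- list(outDir = config$outDir, config = config)
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(config = config[setdiff(names(config), "configHash")],
         config_hash = config$configHash),
    file.path(config$outDir, "provenance.json"), auto_unbox = TRUE,
    digits = NA)

  if ("simulate" %in% stages) out <- stageSimulate(config, out)
  if ("stimuli" %in% stages) out <- stageStimuli(config, out)
  if ("behavior" %in% stages) out <- stageBehavior(config, out)
  if ("neurometric" %in% stages) out <- stageNeurometric(config, out)
  if ("components" %in% stages) out <- stageComponents(config, out)
  if ("decode" %in% stages) out <- stageDecode(config, out)
  if ("report" %in% stages) out <- stageReport(config, out)
  invisible(out)
}

stageSimulate <- function(cfg, out) {
  montage <- makeMontage(cfg$nChannels)
  writeMontage(montage, file.path(cfg$outDir, "montage.tsv"))
  ospec <- observerSpec(conditions = cfg$conditions,
                        blocksPerCondition = cfg$blocksPerCondition,
                        trialsPerBlock = cfg$trialsPerBlock,
                        jitterLevels = cfg$jitterLevels)
  behavior <- list()
  for (i in seq_len(cfg$nSubjects)) {
    id <- sprintf("S%02d", i)
    behavior[[id]] <- simulateBehavior(ospec, seed = childSeed(cfg$seed, i),
                                       subject = id)
  }
  ## plant the EEG jitter effect at the session's behavioral d-prime slope,
  ## realizing the linking hypothesis the analysis is designed to detect
  dpr <- dprimeRegressionTable(do.call(rbind, behavior))
  b1 <- mean(dpr$beta1)
  espec <- eegSpec(nChannels = cfg$nChannels, fsHz = cfg$fsHz,
                   windowMs = cfg$windowMs,
                   effect = list(channels = NULL, windowMs = c(380, 440),
                                 slope = b1,
                                 amplitude = 2 + abs(b1) * log(65)))
  truth <- NULL
  dir.create(file.path(cfg$outDir, "epochs"), showWarnings = FALSE)
  for (i in seq_len(cfg$nSubjects)) {
    id <- sprintf("S%02d", i)
    sim <- simulateEpochs(espec, behavior[[id]], montage,
                          seed = childSeed(cfg$seed, 100L + i))
    writeEpochs(sim$epochs, file.path(cfg$outDir, "epochs", id))
    truth <- truth %||% sim$truth
  }
  beh <- do.call(rbind, behavior)
  writeTsv(beh, file.path(cfg$outDir, "behavior.tsv"), cfg)
  out$montage <- montage
  out$behavior <- beh
  out$truth <- truth
  out
}

stageStimuli <- function(cfg, out) {
  dir.create(file.path(cfg$outDir, "stimuli"), showWarnings = FALSE)
  f <- cfg$displayPx / 1000
  reports <- list()
  for (i in seq_len(cfg$nDisplays)) {
    scfg <- stimulusConfig(
      displayPx = cfg$displayPx, pxPerDeg = cfg$displayPx / 16,
      nContour = max(12, round(43 * f)), nSurface = round(150 * f^2),
      nBackground = round(397 * f^2), minCenterSpacingPx = 30 * f,
      contourJitterSdDeg = 13.8, surfaceJitterSdDeg = 13.8,
      seed = childSeed(cfg$stimSeed, i))
    disp <- generateDisplay(scfg)
    dens <- densityCheck(disp)
    writeDisplayTable(disp, file.path(cfg$outDir, "stimuli",
                                      sprintf("display_%02d.tsv", i)))
    reports[[i]] <- data.frame(display = i, accepted = dens$accepted,
                               t(dens$pairwise_p))
  }
  writeTsv(do.call(rbind, reports),
           file.path(cfg$outDir, "stimuli", "density.tsv"), cfg)
  out$stimuli <- reports
  out
}

stageBehavior <- function(cfg, out) {
  beh <- out$behavior %||%
    readTsv(file.path(cfg$outDir, "behavior.tsv"))
  fits <- list(); rows <- list()
  for (key in unique(paste(beh$subject, beh$condition))) {
    parts <- strsplit(key, " ")[[1]]
    tt <- beh[beh$subject == parts[1] & beh$condition == parts[2], ]
    agg <- stats::aggregate(correct ~ jitter_deg, tt,
                            function(z) c(k = sum(z), n = length(z)))
    fit <- fitProbit(agg$jitter_deg, agg$correct[, "k"], agg$correct[, "n"])
    fits[[key]] <- fit
    calRow <- tryCatch(invertProbit(fit, cfg$targetPc),
                       error = function(e) NA_real_)
    rows[[key]] <- data.frame(
      subject = parts[1], condition = parts[2], threshold = threshold(fit),
      slope = inflectionSlope(fit), guess = fit@guess, lapse = fit@lapse,
      converged = fit@converged, calibrated_jitter = calRow)
  }
  writeTsv(do.call(rbind, rows), file.path(cfg$outDir, "probit_fits.tsv"),
           cfg)
  dpr <- dprimeRegressionTable(beh, byCondition = FALSE)
  writeTsv(dpr, file.path(cfg$outDir, "dprime_regression.tsv"), cfg)
  out$probitFits <- fits
  out$behaviorTables <- dpr
  out
}

loadSubjectEpochs <- function(cfg) {
  dirs <- sort(list.dirs(file.path(cfg$outDir, "epochs"),
                         recursive = FALSE))
  stopIf(!length(dirs), "no epochs found; run the simulate stage first")
  lapply(dirs, readEpochs)
}

cropEpochs <- function(epochs, windowMs) {
  keep <- epochs@times >= windowMs[1] & epochs@times <= windowMs[2]
  new("EpochSet", data = epochs@data[, , keep, drop = FALSE],
      times = epochs@times[keep], lock = epochs@lock,
      channels = epochs@channels, trials = epochs@trials,
      units = epochs@units)
}

slopeMapsFrom <- function(epochsList, cfg, relock = FALSE) {
  maps <- lapply(epochsList, function(ep) {
    if (relock) ep <- relockToResponse(ep, cfg$responseWindowMs)
    else ep <- cropEpochs(ep, cfg$analysisWindowMs)
    fitSlopeMap(preprocessEpochs(ep), predictor = cfg$predictor)
  })
  bindSlopeMaps(maps)
}

#' Combine per-subject slope maps
#'
#' Stacks single-subject [SlopeMap-class] objects (identical grids) into
#' one subjects x channels x time map.
#'
#' @param maps list of [SlopeMap-class] objects.
#' @return a [SlopeMap-class].
#' @export
bindSlopeMaps <- function(maps) {
  stopIf(!length(maps), "no slope maps given")
  ref <- maps[[1]]
  arr <- array(NA_real_, c(sum(vapply(maps, function(m)
    length(m@subjects), integer(1))), length(ref@channels),
    length(ref@times)))
  subjects <- character(0); at <- 0L
  for (m in maps) {
    stopIf(!identical(m@channels, ref@channels) ||
             !isTRUE(all.equal(m@times, ref@times)),
           "slope maps are on different grids")
    k <- length(m@subjects)
    arr[at + seq_len(k), , ] <- m@slopes
    subjects <- c(subjects, m@subjects)
    at <- at + k
  }
  new("SlopeMap", slopes = arr, subjects = subjects,
      channels = ref@channels, times = ref@times,
      predictor = ref@predictor)
}

stageNeurometric <- function(cfg, out) {
  epochsList <- loadSubjectEpochs(cfg)
  montage <- out$montage %||%
    readMontage(file.path(cfg$outDir, "montage.tsv"))
  dpr <- out$behaviorTables %||%
    readTsv(file.path(cfg$outDir, "dprime_regression.tsv"))
  ci <- behavioralSlopeCI(dpr$beta1)

  out$slopeMap <- slopeMapsFrom(epochsList, cfg)
  out$clusters <- clusterPermutation(out$slopeMap, montage,
                                     nPerm = cfg$nPerm,
                                     clusterFormingP = cfg$clusterFormingP,
                                     alphaCluster = cfg$alphaCluster,
                                     seed = childSeed(cfg$seed, 7L))
  out$mask <- matchBehavioralCI(out$clusters, out$slopeMap, ci)
  writeTsv(clusterTable(out$clusters),
           file.path(cfg$outDir, "clusters_stimulus.tsv"), cfg)
  writeMaskTsv(out$mask, file.path(cfg$outDir, "mask_stimulus.tsv"), cfg)

  rsm <- slopeMapsFrom(epochsList, cfg, relock = TRUE)
  out$responseClusters <- clusterPermutation(
    rsm, montage, nPerm = cfg$nPerm,
    clusterFormingP = cfg$clusterFormingP,
    alphaCluster = cfg$alphaCluster, seed = childSeed(cfg$seed, 8L))
  out$responseMask <- matchBehavioralCI(out$responseClusters, rsm, ci)
  writeTsv(clusterTable(out$responseClusters),
           file.path(cfg$outDir, "clusters_response.tsv"), cfg)
  writeMaskTsv(out$responseMask, file.path(cfg$outDir, "mask_response.tsv"),
               cfg)
  out
}

writeMaskTsv <- function(mask, path, cfg) {
  pts <- which(maskMatrix(mask), arr.ind = TRUE)
  df <- data.frame(channel = mask@channels[pts[, 1]],
                   time_ms = mask@times[pts[, 2]])
  writeTsv(df, path, cfg)
}

stageComponents <- function(cfg, out) {
  epochsList <- loadSubjectEpochs(cfg)
  cropped <- lapply(epochsList, function(ep)
    preprocessEpochs(cropEpochs(ep, cfg$analysisWindowMs),
                     zscore = FALSE, rectify = FALSE))
  merged <- mergeEpochSets(cropped)
  peaks <- findComponentPeaks(merged)
  writeTsv(peaks, file.path(cfg$outDir, "peaks.tsv"), cfg)
  models <- lapply(split(peaks, peaks$component), function(pk)
    tryCatch(fitComponentModel(pk), error = function(e) NULL))
  summ <- do.call(rbind, lapply(names(models), function(nm) {
    if (is.null(models[[nm]])) return(NULL)
    data.frame(component = nm, selected = models[[nm]]$selected,
               n_boundary_dropped = models[[nm]]$nDropped)
  }))
  if (!is.null(summ))
    writeTsv(summ, file.path(cfg$outDir, "component_models.tsv"), cfg)
  out$peaks <- peaks
  out$componentModel <- models
  out
}

#' Concatenate EpochSets along trials
#'
#' All inputs must share channels, times, lock and units.
#'
#' @param epochsList list of [EpochSet-class] objects.
#' @return one [EpochSet-class].
#' @export
mergeEpochSets <- function(epochsList) {
  ref <- epochsList[[1]]
  for (ep in epochsList)
    stopIf(!identical(ep@channels, ref@channels) ||
             !isTRUE(all.equal(ep@times, ref@times)) ||
             !identical(ep@lock, ref@lock),
           "EpochSets are incompatible")
  data <- do.call(abind1, lapply(epochsList, function(ep) ep@data))
  trials <- do.call(rbind, lapply(epochsList, function(ep) ep@trials))
  new("EpochSet", data = data, times = ref@times, lock = ref@lock,
      channels = ref@channels, trials = trials, units = ref@units)
}

## rbind for 3-d arrays along the first margin
abind1 <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  out <- array(NA_real_, c(sum(vapply(parts, function(p) dim(p)[1],
                                      integer(1))), d[2], d[3]))
  at <- 0L
  for (p in parts) {
    out[at + seq_len(dim(p)[1]), , ] <- p
    at <- at + dim(p)[1]
  }
  out
}

stageDecode <- function(cfg, out) {
  epochsList <- loadSubjectEpochs(cfg)
  cropped <- lapply(epochsList, function(ep)
    cropEpochs(ep, cfg$analysisWindowMs))
  gamma <- estimateCommonShrinkage(cropped)
  results <- list()
  for (i in seq_along(cropped)) {
    ep <- cropped[[i]]
    keep <- balanceClasses(ep@trials, seed = childSeed(cfg$seed, 200L + i))
    ep <- new("EpochSet", data = ep@data[keep, , , drop = FALSE],
              times = ep@times, lock = ep@lock, channels = ep@channels,
              trials = ep@trials[keep, , drop = FALSE], units = ep@units)
    results[[i]] <- decodeTimecourse(ep, gamma, nFolds = cfg$nFolds,
                                     seed = childSeed(cfg$seed, 300L + i))
  }
  accMat <- do.call(rbind, lapply(results, accuracyTrace))
  out$decoding <- results
  out$gamma <- gamma
  out$accuracyClusters <- temporalClusterTest(
    accMat, nPerm = cfg$nPerm, seed = childSeed(cfg$seed, 9L),
    times = cropped[[1]]@times)
  acc <- data.frame(time_ms = cropped[[1]]@times,
                    accuracy = colMeans(accMat))
  writeTsv(acc, file.path(cfg$outDir, "decoding_accuracy.tsv"), cfg)
  writeTsv(clusterTable(out$accuracyClusters),
           file.path(cfg$outDir, "decoding_clusters.tsv"), cfg)
  out
}

stageReport <- function(cfg, out) {
  lines <- c(sprintf("config_hash\t%s", cfg$configHash),
             sprintf("seed\t%s", cfg$seed))
  if (!is.null(out$clusters))
    lines <- c(lines, sprintf("stimulus_clusters_significant\t%d",
                              sum(clusterTable(out$clusters)$significant)),
               sprintf("stimulus_mask_points\t%d", sum(maskMatrix(out$mask))))
  if (!is.null(out$responseClusters))
    lines <- c(lines,
               sprintf("response_clusters_significant\t%d",
                       sum(clusterTable(out$responseClusters)$significant)),
               sprintf("response_mask_points\t%d",
                       sum(maskMatrix(out$responseMask))))
  if (!is.null(out$gamma))
    lines <- c(lines, sprintf("shrinkage_gamma\t%.6f", out$gamma))
  writeLines(lines, file.path(cfg$outDir, "report.tsv"))
  if (isTRUE(cfg$figures) && capabilities("png") &&
      !is.null(out$slopeMap)) {
    grDevices::png(file.path(cfg$outDir, "slope_raster.png"), 700, 500)
    meanSlope <- apply(slopeArray(out$slopeMap), c(2, 3), mean)
    graphics::image(out$slopeMap@times, seq_along(out$slopeMap@channels),
                    t(meanSlope), xlab = "time (ms)", ylab = "channel",
                    main = "mean slope (z / log-deg)")
    grDevices::dev.off()
  }
  out$report <- lines
  out
}
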