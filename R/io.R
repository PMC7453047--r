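## The native epochs container (JSON metadata + flat float64 tensor + TSV
## trial table), montage files, and run configuration handling.

CONTAINER_VERSION <- "1.0"

vlError <- function(class, ...) {
  stop(errorCondition(paste0(...), class = c(class, "veplinkError")))
}

#' Write an EpochSet to its on-disk container
#'
#' A directory holding `metadata.json` (version, sampling rate, time axis,
#' channel names, lock, units, tensor dimensions), `data.bin` (row-major
#' little-endian float64 tensor in trial x channel x time order) and
#' `trials.tsv`.  The round trip through [readEpochs()] is lossless.
#'
#' @param epochs an [EpochSet-class].
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
writeEpochs <- function(epochs, path) {
  stopifnot(is(epochs, "EpochSet"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  d <- dim(epochs@data)
  meta <- list(version = CONTAINER_VERSION, fs_hz = samplingRate(epochs),
               times_ms = epochs@times, channels = epochs@channels,
               lock = epochs@lock, units = epochs@units,
               dims = d, order = "trial_channel_time")
  jsonlite::write_json(meta, file.path(path, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  con <- file(file.path(path, "data.bin"), "wb")
  on.exit(close(con))
  writeBin(as.vector(aperm(epochs@data, c(3, 2, 1))), con, size = 8,
           endian = "little")
  write.table(epochs@trials, file.path(path, "trials.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an EpochSet container
#'
#' Validates the container version, the declared dimension order and the
#' tensor size before reconstructing the [EpochSet-class]; corrupt or
#' inconsistent containers raise classed errors (`veplinkMissingFile`,
#' `veplinkShapeMismatch`, `veplinkUnsupportedVersion`) rather than
#' returning garbage.
#'
#' @param path container directory.
#' @return an [EpochSet-class].
#' @export
readEpochs <- function(path) {
  for (f in c("metadata.json", "data.bin", "trials.tsv"))
    if (!file.exists(file.path(path, f)))
      vlError("veplinkMissingFile", "missing container member: ", f)
  meta <- jsonlite::read_json(file.path(path, "metadata.json"),
                              simplifyVector = TRUE)
  if (!identical(meta$version, CONTAINER_VERSION))
    vlError("veplinkUnsupportedVersion", "unsupported container version: ",
            meta$version %||% "<absent>")
  if (!identical(meta$order, "trial_channel_time"))
    vlError("veplinkShapeMismatch", "unsupported dimension order: ",
            meta$order %||% "<absent>")
  d <- as.integer(meta$dims)
  if (length(d) != 3 || length(meta$channels) != d[2] ||
      length(meta$times_ms) != d[3])
    vlError("veplinkShapeMismatch",
            "metadata dims inconsistent with channels/times")
  nBytes <- file.info(file.path(path, "data.bin"))$size
  if (nBytes != prod(d) * 8)
    vlError("veplinkShapeMismatch", "data.bin holds ", nBytes,
            " bytes but metadata declares ", prod(d) * 8)
  con <- file(file.path(path, "data.bin"), "rb")
  on.exit(close(con))
  raw <- readBin(con, "double", n = prod(d), size = 8, endian = "little")
  data <- aperm(array(raw, dim = d[c(3, 2, 1)]), c(3, 2, 1))
  trials <- read.delim(file.path(path, "trials.tsv"),
                       stringsAsFactors = FALSE)
  if (nrow(trials) != d[1])
    vlError("veplinkShapeMismatch", "trial table has ", nrow(trials),
            " rows but metadata declares ", d[1])
  new("EpochSet", data = data, times = as.numeric(meta$times_ms),
      lock = meta$lock, channels = as.character(meta$channels),
      trials = trials, units = meta$units)
}

#' Write / read a montage file
#'
#' Tab-separated text with columns `name`, `x`, `y`, `z`.  Adjacency is
#' recomputed on read from the stored positions with the given threshold
#' (default: the 6th-nearest-neighbor rule of [makeMontage()]), so the
#' round trip reproduces the adjacency exactly when the same threshold is
#' used.
#'
#' @param montage a [Montage-class].
#' @param path file path.
#' @param threshold adjacency threshold for `readMontage`; `NULL` for the
#'   default rule.
#' @return `readMontage` returns a [Montage-class].
#' @export
writeMontage <- function(montage, path) {
  stopifnot(is(montage, "Montage"))
  ## full double precision so adjacency recomputed on read is identical
  df <- data.frame(name = montage@channels,
                   x = sprintf("%.17g", montage@positions[, 1]),
                   y = sprintf("%.17g", montage@positions[, 2]),
                   z = sprintf("%.17g", montage@positions[, 3]))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeMontage
#' @export
readMontage <- function(path, threshold = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  pos <- as.matrix(df[, c("x", "y", "z")])
  rownames(pos) <- NULL
  colnames(pos) <- c("x", "y", "z")
  D <- as.matrix(dist(pos))
  if (is.null(threshold)) {
    k <- min(6L, nrow(pos) - 1L)
    threshold <- median(apply(D, 1, function(d) sort(d)[k + 1L]))
  }
  adj <- D < threshold
  diag(adj) <- FALSE
  dimnames(adj) <- NULL
  new("Montage", channels = df$name, positions = pos, adjacency = adj,
      threshold = threshold)
}

runConfigKeys <- function() {
  c("outDir", "seed", "stages", "nSubjects", "nChannels", "fsHz",
    "windowMs", "trialsPerBlock", "blocksPerCondition", "conditions",
    "jitterLevels", "nPerm", "clusterFormingP", "alphaCluster",
    "predictor", "analysisWindowMs", "responseWindowMs", "nFolds",
    "targetPc", "nDisplays", "stimSeed", "displayPx", "figures")
}

#' Read and validate a run configuration
#'
#' YAML file mirroring [demoRunConfig()]; unknown keys are rejected.  The
#' returned list carries a `configHash` (MD5 of the canonical JSON
#' serialization) that [runPipeline()] writes into every output for
#' provenance.
#'
#' @param path YAML file path.
#' @return validated config list with `configHash` attached.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), runConfigKeys())
  stopIf(length(unknown) > 0, "unknown config key(s): ",
         paste(unknown, collapse = ", "))
  finalizeRunConfig(cfg)
}

finalizeRunConfig <- function(cfg) {
  cfg <- modifyList(demoRunConfig(), cfg)
  cfg$configHash <- configHash(cfg)
  cfg
}

configHash <- function(cfg) {
  cfg$configHash <- NULL
  cfg$outDir <- NULL   # the hash identifies the analysis, not its location
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg[order(names(cfg))], auto_unbox = TRUE,
                              digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

#' Demonstration run configuration
#'
#' A small but complete configuration for [runPipeline()]: 8 subjects,
#' 24 channels at 200 Hz, one block of 144 trials per condition, planted
#' effect and class signal at the default locations.  Intended for demos
#' and tests; scale up for real use.
#'
#' @return config list (pass through [finalizeRunConfig()] happens inside
#'   [runPipeline()]).
#' @export
demoRunConfig <- function() {
  list(outDir = tempfile("veplink_run_"), seed = 1L,
       stages = c("simulate", "stimuli", "behavior", "neurometric",
                  "components", "decode", "report"),
       nSubjects = 10, nChannels = 24, fsHz = 200,
       windowMs = c(-1000, 1000), trialsPerBlock = 144,
       blocksPerCondition = 1,
       conditions = c("contour_fixed", "surface_fixed"),
       jitterLevels = jitterLevels(), nPerm = 250,
       clusterFormingP = 0.01, alphaCluster = 0.01,
       predictor = "log_jitter", analysisWindowMs = c(-100, 500),
       responseWindowMs = c(-1000, 0), nFolds = 5, targetPc = 0.68,
       nDisplays = 3, stimSeed = 1L, displayPx = 400, figures = FALSE)
}
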