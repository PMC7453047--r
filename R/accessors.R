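## Accessor generics and show methods for the core containers.

#' Channel names of a container
#' @param x an [EpochSet-class], [Montage-class], [SlopeMap-class] or other
#'   channelled object.
#' @return character vector of channel names.
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname channelNames
#' @export
setMethod("channelNames", "EpochSet", function(x) x@channels)
#' @rdname channelNames
#' @export
setMethod("channelNames", "Montage", function(x) x@channels)
#' @rdname channelNames
#' @export
setMethod("channelNames", "SlopeMap", function(x) x@channels)

#' Amplitude tensor of an EpochSet
#' @param x an [EpochSet-class].
#' @return numeric array, trials x channels x time.
#' @export
epochData <- function(x) {
  stopifnot(is(x, "EpochSet"))
  x@data
}

#' Time axis of an EpochSet (ms relative to the lock event)
#' @param x an [EpochSet-class].
#' @return numeric vector of sample times, ms.
#' @export
epochTimes <- function(x) {
  stopifnot(is(x, "EpochSet"))
  x@times
}

#' Trial table of an EpochSet
#' @param x an [EpochSet-class].
#' @return `data.frame`, one row per trial.
#' @export
epochTrials <- function(x) {
  stopifnot(is(x, "EpochSet"))
  x@trials
}

#' Sampling rate of an EpochSet in Hz
#' @param x an [EpochSet-class].
#' @return sampling rate, Hz.
#' @export
samplingRate <- function(x) {
  stopifnot(is(x, "EpochSet"))
  if (length(x@times) < 2) return(NA_real_)
  1000 / (x@times[2] - x@times[1])
}

#' Number of trials in an EpochSet
#' @param x an [EpochSet-class].
#' @return integer trial count.
#' @export
nTrials <- function(x) {
  stopifnot(is(x, "EpochSet"))
  dim(x@data)[1]
}

#' Element table of a StimulusDisplay
#' @param x a [StimulusDisplay-class].
#' @return `data.frame` of element positions, orientations and regions.
#' @export
displayElements <- function(x) {
  stopifnot(is(x, "StimulusDisplay"))
  x@elements
}

#' Slope array of a SlopeMap
#' @param x a [SlopeMap-class].
#' @return numeric array, subjects x channels x time.
#' @export
slopeArray <- function(x) {
  stopifnot(is(x, "SlopeMap"))
  x@slopes
}

#' Cluster summary table
#'
#' One row per cluster: id, sign, mass, p-value and spatiotemporal extent.
#'
#' @param x a [ClusterResult-class].
#' @return `data.frame` with columns `id`, `sign`, `mass`, `p`,
#'   `n_points`, `n_channels`, `t_min_ms`, `t_max_ms`, `significant`.
#' @export
clusterTable <- function(x) {
  stopifnot(is(x, "ClusterResult"))
  if (!length(x@clusters)) {
    return(data.frame(id = integer(), sign = integer(), mass = numeric(),
                      p = numeric(), n_points = integer(),
                      n_channels = integer(), t_min_ms = numeric(),
                      t_max_ms = numeric(), significant = logical()))
  }
  do.call(rbind, lapply(x@clusters, function(cl) {
    data.frame(id = cl$id, sign = cl$sign, mass = cl$mass, p = cl$p,
               n_points = nrow(cl$members),
               n_channels = length(unique(cl$members[, 1])),
               t_min_ms = min(x@times[cl$members[, 2]]),
               t_max_ms = max(x@times[cl$members[, 2]]),
               significant = cl$p <= x@alphaCluster)
  }))
}

#' Logical mask of a MatchMask
#' @param x a [MatchMask-class].
#' @return logical matrix, channels x time.
#' @export
maskMatrix <- function(x) {
  stopifnot(is(x, "MatchMask"))
  x@mask
}

#' Accuracy trace of a DecodingResult
#' @param x a [DecodingResult-class].
#' @return numeric vector of per-timepoint CV accuracies.
#' @export
accuracyTrace <- function(x) {
  stopifnot(is(x, "DecodingResult"))
  x@accuracy
}

#' Threshold (inflection point) of a psychometric fit
#' @param fit a [PsychometricFit-class].
#' @return jitter (degrees) at the inflection point, the midpoint between
#'   the asymptotes.
#' @export
threshold <- function(fit) {
  stopifnot(is(fit, "PsychometricFit"))
  fit@mu
}

#' Gradient of the psychometric curve at its inflection point
#' @param fit a [PsychometricFit-class].
#' @return slope in proportion-correct per degree (negative).
#' @export
inflectionSlope <- function(fit) {
  stopifnot(is(fit, "PsychometricFit"))
  -(1 - fit@guess - fit@lapse) * dnorm(0) / fit@scale
}

setMethod("show", "StimulusDisplay", function(object) {
  cnt <- table(object@elements$region)
  cat("StimulusDisplay:", nrow(object@elements), "elements (",
      paste(names(cnt), as.integer(cnt), collapse = ", "), ")\n")
  cat("  condition:", object@config@condition,
      " ellipse:", object@config@ellipseOrientation,
      " center(px):", paste(round(object@centerPx, 1), collapse = ", "), "\n")
  if (length(object@density))
    cat("  density check:", if (isTRUE(object@density$accepted))
      "accepted" else "rejected", "\n")
})

setMethod("show", "PsychometricFit", function(object) {
  cat("PsychometricFit (4-parameter probit)\n")
  cat(sprintf("  threshold %.2f deg, slope %.4f /deg, guess %.3f, lapse %.3f\n",
              object@mu, inflectionSlope(object), object@guess, object@lapse))
  cat(sprintf("  logLik %.2f, converged: %s\n", object@loglik,
              object@converged))
})

setMethod("show", "DprimeRegression", function(object) {
  cat("DprimeRegression: log d' ~ beta0 + beta1 * log(jitter)\n")
  cat(sprintf("  beta0 %.3f, beta1 %.3f [%.3f, %.3f], sigma %.3f, n = %d\n",
              object@beta0, object@beta1, object@ciBeta1[1],
              object@ciBeta1[2], object@sigma, as.integer(object@nPoints)))
})

setMethod("show", "Montage", function(object) {
  deg <- rowSums(object@adjacency)
  cat(sprintf("Montage: %d channels, median neighbor count %d (threshold %.3f)\n",
              length(object@channels), as.integer(median(deg)),
              object@threshold))
})

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@data)
  cat(sprintf("EpochSet: %d trials x %d channels x %d samples (%s-locked)\n",
              d[1], d[2], d[3], object@lock))
  cat(sprintf("  %.0f Hz, %g to %g ms, units: %s\n", samplingRate(object),
              min(object@times), max(object@times), object@units))
})

setMethod("show", "SlopeMap", function(object) {
  d <- dim(object@slopes)
  cat(sprintf("SlopeMap: %d subjects x %d channels x %d samples (predictor: %s)\n",
              d[1], d[2], d[3], object@predictor))
})

setMethod("show", "ClusterResult", function(object) {
  tab <- clusterTable(object)
  cat(sprintf("ClusterResult: %d cluster(s), %d significant at alpha %.3g (%d permutations)\n",
              nrow(tab), sum(tab$significant), object@alphaCluster,
              as.integer(object@nPerm)))
})

setMethod("show", "MatchMask", function(object) {
  cat(sprintf("MatchMask (%s mode): %d of %d points retained; behavioral CI [%.3f, %.3f]\n",
              object@mode, sum(object@mask), length(object@mask),
              object@ci[1], object@ci[2]))
})

setMethod("show", "DecodingResult", function(object) {
  cat(sprintf("DecodingResult: %d timepoints, gamma %.4g, %d-fold CV; peak accuracy %.3f at %g ms\n",
              length(object@times), object@gamma, as.integer(object@nFolds),
              max(object@accuracy), object@times[which.max(object@accuracy)]))
})
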