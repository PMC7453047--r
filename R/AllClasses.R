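#' @import methods
#' @importFrom stats approx coef confint cor dist dnorm lm logLik mad median
#'   optim pnorm pt qnorm qt quantile rbinom rlnorm rnorm runif sd setNames
#'   t.test var vcov
#' @importFrom utils head modifyList read.delim write.table
#' @useDynLib veplink, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## ---------------------------------------------------------------------------
## Stimulus generation classes
## ---------------------------------------------------------------------------

#' Configuration for a Gaborized ellipse display
#'
#' Holds the full parameterization of one stimulus display: geometry of the
#' embedded ellipse, element counts per region, cue (orientation jitter)
#' settings, and Gabor carrier/envelope parameters.  Construct with
#' [stimulusConfig()], which supplies the default design (590 elements split
#' 43 contour / 150 surface / 397 background, axis ratio 1.2).
#'
#' Orientations are in degrees, 0 = vertical, positive clockwise.
#'
#' @slot displayPx integer, pixels per side of the square display.
#' @slot pxPerDeg pixels per degree of visual angle.
#' @slot nContour,nSurface,nBackground element counts per region.
#' @slot ellipseMajorDeg major axis length of the ellipse, degrees.
#' @slot axisRatio major/minor axis ratio (> 1).
#' @slot ellipseOrientation `"vertical"` or `"horizontal"`.
#' @slot condition `"contour_only"`, `"surface_only"` or `"combined"`.
#' @slot contourJitterSdDeg,surfaceJitterSdDeg SD of the Gaussian orientation
#'   jitter applied to active cue elements, degrees.
#' @slot surfaceBaseOrientationDeg base orientation of iso-oriented surface
#'   elements (degrees from vertical).
#' @slot nonsurfaceBaseOrientationDeg orientation of contour/background
#'   elements in the surface-only condition.
#' @slot centerOffsetDeg magnitude of the random ellipse-center displacement.
#' @slot gaborSfCycPerDeg carrier spatial frequency, cycles per degree.
#' @slot gaborContrast Michelson contrast of each element, in \[0, 1\].
#' @slot gaborEnvelopeSdArcmin SD of the circular Gaussian envelope, arcmin.
#' @slot minCenterSpacingPx minimum pairwise center distance, pixels.
#' @slot seed integer RNG seed.
#' @seealso [generateDisplay()], [renderDisplay()]
#' @export
setClass("StimulusConfig", representation(
  displayPx = "numeric", pxPerDeg = "numeric",
  nContour = "numeric", nSurface = "numeric", nBackground = "numeric",
  ellipseMajorDeg = "numeric", axisRatio = "numeric",
  ellipseOrientation = "character", condition = "character",
  contourJitterSdDeg = "numeric", surfaceJitterSdDeg = "numeric",
  surfaceBaseOrientationDeg = "numeric",
  nonsurfaceBaseOrientationDeg = "numeric",
  centerOffsetDeg = "numeric",
  gaborSfCycPerDeg = "numeric", gaborContrast = "numeric",
  gaborEnvelopeSdArcmin = "numeric",
  minCenterSpacingPx = "numeric", seed = "numeric"))

setValidity("StimulusConfig", function(object) {
  msg <- character()
  if (object@axisRatio <= 1) msg <- c(msg, "axisRatio must be > 1")
  if (object@gaborContrast < 0 || object@gaborContrast > 1)
    msg <- c(msg, "gaborContrast must lie in [0, 1]")
  if (object@contourJitterSdDeg < 0 || object@surfaceJitterSdDeg < 0)
    msg <- c(msg, "jitter SDs must be >= 0")
  if (any(c(object@nContour, object@nSurface, object@nBackground) < 0))
    msg <- c(msg, "element counts must be >= 0")
  if (!object@condition %in% c("contour_only", "surface_only", "combined"))
    msg <- c(msg, "condition must be contour_only, surface_only or combined")
  if (!object@ellipseOrientation %in% c("vertical", "horizontal"))
    msg <- c(msg, "ellipseOrientation must be vertical or horizontal")
  if (object@displayPx < 10) msg <- c(msg, "displayPx too small")
  if (length(msg)) msg else TRUE
})

#' A generated Gaborized ellipse display
#'
#' One stimulus display: the generating [StimulusConfig-class], the element
#' table (positions, orientations, region labels, and for contour elements
#' the ellipse-tangent orientation) and the displaced ellipse center.  The
#' optional `density` slot holds the result of [densityCheck()].
#'
#' @slot config the generating configuration.
#' @slot elements `data.frame` with columns `x_px`, `y_px`,
#'   `orientation_deg`, `region`, `tangent_deg`.
#' @slot centerPx numeric length 2, displaced ellipse center (pixels).
#' @slot density list as returned by [densityCheck()], or empty.
#' @export
setClass("StimulusDisplay", representation(
  config = "StimulusConfig", elements = "data.frame",
  centerPx = "numeric", density = "list"))

setValidity("StimulusDisplay", function(object) {
  el <- object@elements
  need <- c("x_px", "y_px", "orientation_deg", "region", "tangent_deg")
  if (!all(need %in% names(el)))
    return("elements must have columns x_px, y_px, orientation_deg, region, tangent_deg")
  cfg <- object@config
  cnt <- table(factor(el$region, levels = c("contour", "surface", "background")))
  if (cnt[["contour"]] != cfg@nContour || cnt[["surface"]] != cfg@nSurface ||
      cnt[["background"]] != cfg@nBackground)
    return("region counts do not match config")
  if (any(el$x_px < 0 | el$x_px > cfg@displayPx | el$y_px < 0 |
          el$y_px > cfg@displayPx))
    return("element positions outside the display square")
  TRUE
})

## ---------------------------------------------------------------------------
## Psychometric classes
## ---------------------------------------------------------------------------

#' Four-parameter probit psychometric fit
#'
#' Maximum-likelihood fit of
#' \deqn{P(\mathrm{correct} \mid j) = g + (1 - g - l)\,\Phi((\mu - j)/s)}
#' to per-level correct/total counts, where \eqn{j} is the orientation jitter
#' SD (degrees), \eqn{g} the guess rate (lower asymptote), \eqn{l} the lapse
#' rate (upper-asymptote deficit), \eqn{\mu} the location and \eqn{s} the
#' scale.  The threshold is the inflection point \eqn{\mu} (performance
#' midway between the asymptotes) and the slope is the gradient of the curve
#' there, \eqn{-(1-g-l)\,\phi(0)/s} (negative: performance falls with
#' jitter).
#'
#' @slot mu,scale probit location (deg) and scale (deg).
#' @slot guess,lapse asymptote parameters, each in \[0, 0.5\].
#' @slot loglik maximized binomial log-likelihood.
#' @slot converged logical; `FALSE` for non-identifiable data.
#' @slot data the fitted per-level counts.
#' @seealso [fitProbit()], [invertProbit()], [evaluateProbit()]
#' @export
setClass("PsychometricFit", representation(
  mu = "numeric", scale = "numeric", guess = "numeric", lapse = "numeric",
  loglik = "numeric", converged = "logical", data = "data.frame"))

setValidity("PsychometricFit", function(object) {
  if (object@guess < 0 || object@guess > 0.5) return("guess must be in [0, 0.5]")
  if (object@lapse < 0 || object@lapse > 0.5) return("lapse must be in [0, 0.5]")
  if (object@scale <= 0) return("scale must be > 0")
  TRUE
})

#' Log-log d-prime/jitter regression
#'
#' Ordinary least squares of \eqn{\log d'} on \eqn{\log} jitter:
#' \eqn{\log d' = \beta_0 + \beta_1 \log j + \epsilon},
#' \eqn{\epsilon \sim N(0, \sigma)}.  This linear re-expression of the
#' psychometric function is the behavioral side of the neurometric linking
#' analysis: its slope confidence interval is the band against which EEG
#' slope maps are matched.
#'
#' @slot beta0,beta1 intercept and slope.
#' @slot sigma residual SD.
#' @slot ciBeta1 t-based 95 percent confidence interval for `beta1`.
#' @slot nPoints number of (level, d-prime) points used.
#' @seealso [fitDprimeRegression()], [matchBehavioralCI()]
#' @export
setClass("DprimeRegression", representation(
  beta0 = "numeric", beta1 = "numeric", sigma = "numeric",
  ciBeta1 = "numeric", nPoints = "numeric"))

setValidity("DprimeRegression", function(object) {
  if (length(object@ciBeta1) != 2) return("ciBeta1 must have length 2")
  if (object@beta1 < object@ciBeta1[1] || object@beta1 > object@ciBeta1[2])
    return("ciBeta1 must contain beta1")
  TRUE
})

## ---------------------------------------------------------------------------
## EEG containers
## ---------------------------------------------------------------------------

#' Electrode montage
#'
#' Channel names, 3D positions (unit sphere by default) and a symmetric,
#' irreflexive spatial adjacency used by the cluster-based permutation test.
#'
#' @slot channels character channel names.
#' @slot positions numeric matrix, channels x 3.
#' @slot adjacency logical matrix, channels x channels.
#' @slot threshold the distance threshold that defined the adjacency.
#' @seealso [makeMontage()], [clusterPermutation()]
#' @export
setClass("Montage", representation(
  channels = "character", positions = "matrix", adjacency = "matrix",
  threshold = "numeric"))

setValidity("Montage", function(object) {
  n <- length(object@channels)
  if (anyDuplicated(object@channels)) return("channel names must be unique")
  if (!all(dim(object@positions) == c(n, 3)))
    return("positions must be channels x 3")
  if (!all(dim(object@adjacency) == c(n, n)))
    return("adjacency must be channels x channels")
  if (!is.logical(object@adjacency)) return("adjacency must be logical")
  if (!identical(object@adjacency, t(object@adjacency)))
    return("adjacency must be symmetric")
  if (any(diag(object@adjacency))) return("adjacency must be irreflexive")
  if (n >= 2 && any(rowSums(object@adjacency) < 1))
    return("every channel needs at least one neighbor (isolated channels)")
  TRUE
})

#' Epoched multi-channel time series
#'
#' A trials x channels x time amplitude tensor with its trial table and time
#' axis, locked to stimulus onset or to the behavioral response.
#'
#' @slot data numeric array, trials x channels x time.
#' @slot times time axis in ms relative to the lock event, uniform step.
#' @slot lock `"stimulus"` or `"response"`.
#' @slot channels channel names.
#' @slot trials `data.frame` with one row per trial (jitter, condition,
#'   orientation, response, correctness, RT, subject, ...).
#' @slot units amplitude units, e.g. `"uV"` or `"z"`.
#' @seealso [simulateEpochs()], [preprocessEpochs()], [readEpochs()]
#' @export
setClass("EpochSet", representation(
  data = "array", times = "numeric", lock = "character",
  channels = "character", trials = "data.frame", units = "character"))

setValidity("EpochSet", function(object) {
  d <- dim(object@data)
  if (length(d) != 3) return("data must be a 3-d array (trials x channels x time)")
  if (d[1] != nrow(object@trials)) return("trial table length != dim(data)[1]")
  if (d[2] != length(object@channels)) return("channels length != dim(data)[2]")
  if (d[3] != length(object@times)) return("times length != dim(data)[3]")
  if (length(object@times) >= 2) {
    dt <- diff(object@times)
    if (any(dt <= 0)) return("times must be strictly increasing")
    if (max(abs(dt - dt[1])) > 1e-6) return("times must have a uniform step")
  }
  if (!object@lock %in% c("stimulus", "response"))
    return("lock must be stimulus or response")
  TRUE
})

## ---------------------------------------------------------------------------
## Neurometric result classes
## ---------------------------------------------------------------------------

#' Per-subject slope maps
#'
#' Per (subject, channel, timepoint) OLS slopes of single-trial rectified
#' amplitude on the jitter predictor (log jitter by default), in z-units per
#' log-degree.
#'
#' @slot slopes numeric array, subjects x channels x time.
#' @slot subjects,channels,times dimension labels.
#' @slot predictor description of the regressor used.
#' @seealso [fitSlopeMap()], [clusterPermutation()]
#' @export
setClass("SlopeMap", representation(
  slopes = "array", subjects = "character", channels = "character",
  times = "numeric", predictor = "character"))

setValidity("SlopeMap", function(object) {
  d <- dim(object@slopes)
  if (length(d) != 3) return("slopes must be subjects x channels x time")
  if (d[1] != length(object@subjects)) return("subjects length mismatch")
  if (d[2] != length(object@channels)) return("channels length mismatch")
  if (d[3] != length(object@times)) return("times length mismatch")
  TRUE
})

#' Spatiotemporal cluster-based permutation result
#'
#' Suprathreshold points of the group-level one-sample t map, clustered by
#' montage adjacency and temporal contiguity with consistent sign, with
#' cluster-mass p-values from a sign-flip permutation null.
#'
#' @slot clusters list; each element has `id`, `sign`, `mass`, `p`,
#'   `channels`, `times`, and the point index matrix `members`.
#' @slot tmap observed t matrix (channels x time).
#' @slot labels integer matrix of cluster ids (0 = subthreshold).
#' @slot tThreshold cluster-forming |t| threshold.
#' @slot clusterFormingP,alphaCluster,nPerm,seed test parameters.
#' @slot nullMax permutation distribution of the maximum cluster mass.
#' @slot channels,times grid labels.
#' @seealso [clusterPermutation()], [matchBehavioralCI()]
#' @export
setClass("ClusterResult", representation(
  clusters = "list", tmap = "matrix", labels = "matrix",
  tThreshold = "numeric", clusterFormingP = "numeric",
  alphaCluster = "numeric", nPerm = "numeric", seed = "numeric",
  nullMax = "numeric", channels = "character", times = "numeric"))

#' Behaviorally matched subset of significant points
#'
#' Boolean channels x time mask of points inside significant clusters whose
#' cross-subject mean EEG slope falls within the behavioral d-prime slope
#' confidence interval.
#'
#' @slot mask logical matrix, channels x time.
#' @slot ci the behavioral 95 percent CI (lo, hi) used.
#' @slot mode `"point"` or `"cluster"` retention rule.
#' @slot channels,times grid labels.
#' @seealso [matchBehavioralCI()]
#' @export
setClass("MatchMask", representation(
  mask = "matrix", ci = "numeric", mode = "character",
  channels = "character", times = "numeric"))

#' Per-timepoint decoding result
#'
#' Cross-validated LDA accuracy over time, classifier weights and
#' activation-pattern projections, for one subject.
#'
#' @slot accuracy numeric per-timepoint mean CV accuracy.
#' @slot weights,patterns numeric matrices, channels x time.
#' @slot gamma shrinkage coefficient used.
#' @slot nFolds,seed CV parameters.
#' @slot channels,times dimension labels.
#' @seealso [decodeTimecourse()], [temporalClusterTest()]
#' @export
setClass("DecodingResult", representation(
  accuracy = "numeric", weights = "matrix", patterns = "matrix",
  gamma = "numeric", nFolds = "numeric", seed = "numeric",
  channels = "character", times = "numeric"))

setValidity("DecodingResult", function(object) {
  if (any(object@accuracy < 0 | object@accuracy > 1))
    return("accuracy must lie in [0, 1]")
  if (!all(is.finite(object@patterns))) return("patterns must be finite")
  TRUE
})
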