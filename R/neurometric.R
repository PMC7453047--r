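## The core linking analysis: preprocessing (average reference, pooled
## z-scoring, rectification), per-point single-trial regression of
## amplitude on (log) jitter, group-level spatiotemporal cluster-based
## permutation inference, retention of points matching the behavioral
## d-prime slope CI, and response-locked re-epoching.

#' Preprocess an EpochSet for the slope analysis
#'
#' Applies, in fixed order: (1) average reference -- subtract the
#' cross-channel mean at every trial and timepoint; (2) z-scoring with one
#' mean and SD per subject pooled over all of that subject's trials,
#' channels and timepoints; (3) rectification (absolute value, so both
#' polarities count as activity).  Each stage can be toggled off.
#'
#' @param epochs an [EpochSet-class].
#' @param reference,zscore,rectify stage toggles.
#' @return the preprocessed [EpochSet-class] (units become `"z"` after
#'   z-scoring).
#' @export
preprocessEpochs <- function(epochs, reference = TRUE, zscore = TRUE,
                             rectify = TRUE) {
  stopifnot(is(epochs, "EpochSet"))
  x <- epochs@data
  d <- dim(x)
  stopIf(d[2] < 2, "average reference needs >= 2 channels")
  units <- epochs@units
  if (reference) {
    m <- colMeans(aperm(x, c(2, 1, 3)))            # trials x time
    x <- x - aperm(array(m, c(d[1], d[3], d[2])), c(1, 3, 2))
  }
  if (zscore) {
    subj <- epochs@trials$subject %||% rep("all", d[1])
    for (s in unique(subj)) {
      rows <- which(subj == s)
      v <- x[rows, , , drop = FALSE]
      sdv <- sd(v)
      stopIf(!is.finite(sdv) || sdv == 0,
             "zero variance in subject ", s, "; cannot z-score")
      x[rows, , ] <- (v - mean(v)) / sdv
    }
    units <- "z"
  }
  if (rectify) x <- abs(x)
  initialize(epochs, data = x, units = units)
}

#' Per-point regression of amplitude on jitter
#'
#' For every subject, channel and timepoint, the OLS slope of single-trial
#' (rectified) amplitude on the predictor -- log jitter by default, so the
#' slopes are commensurate with the behavioral log-log d-prime regression.
#' Computed in closed form from centered cross-products, identical to
#' per-point `lm()` fits.
#'
#' @param epochs a preprocessed [EpochSet-class]; trials must carry
#'   `jitter_deg` (and `subject`).
#' @param predictor `"log_jitter"` (default) or `"jitter"`.
#' @param levelMeans if `TRUE`, regress the six per-level mean amplitudes
#'   instead of single trials (same expectation, different df).
#' @return a [SlopeMap-class], subjects x channels x time.
#' @export
fitSlopeMap <- function(epochs, predictor = c("log_jitter", "jitter"),
                        levelMeans = FALSE) {
  stopifnot(is(epochs, "EpochSet"))
  predictor <- match.arg(predictor)
  tr <- epochs@trials
  stopIf(is.null(tr$jitter_deg), "trial table lacks jitter_deg")
  stopIf(length(unique(tr$jitter_deg)) < 2,
         "need >= 2 distinct jitter levels")
  subj <- as.character(tr$subject %||% rep("S01", nrow(tr)))
  subjects <- unique(subj)
  d <- dim(epochs@data)
  slopes <- array(NA_real_, c(length(subjects), d[2], d[3]))
  for (si in seq_along(subjects)) {
    rows <- which(subj == subjects[si])
    X <- epochs@data[rows, , , drop = FALSE]
    dim(X) <- c(length(rows), d[2] * d[3])
    p <- tr$jitter_deg[rows]
    if (levelMeans) {
      lev <- sort(unique(p))
      X <- t(vapply(lev, function(l) colMeans(X[p == l, , drop = FALSE]),
                    numeric(ncol(X))))
      p <- lev
    }
    xv <- if (predictor == "log_jitter") log(p) else p
    xc <- xv - mean(xv)
    b <- drop(crossprod(X, xc)) / sum(xc^2)
    slopes[si, , ] <- matrix(b, d[2], d[3])
  }
  new("SlopeMap", slopes = slopes, subjects = subjects,
      channels = epochs@channels, times = epochs@times,
      predictor = predictor)
}

## Montage adjacency as a 0-based integer list aligned to `channels`.
adjacencyList0 <- function(montage, channels) {
  idx <- match(channels, montage@channels)
  stopIf(anyNA(idx), "montage does not cover all slope-map channels")
  A <- montage@adjacency[idx, idx, drop = FALSE]
  lapply(seq_along(channels), function(i) which(A[i, ]) - 1L)
}

#' Group-level spatiotemporal cluster-based permutation test
#'
#' One-sample t statistics across subjects at every (channel, timepoint);
#' suprathreshold points (|t| above the two-tailed cluster-forming
#' quantile) are clustered by montage adjacency and temporal contiguity
#' with consistent sign, and each cluster's mass (sum of |t|) is compared
#' to the permutation distribution of the maximum cluster mass under
#' random per-subject sign flips.  Cluster p-values use the add-one rule
#' `(1 + #null >= observed) / (1 + nPerm)`; the null maximum is taken over
#' both signs, so `p <= alphaCluster` controls the two-tailed family-wise
#' error at `alphaCluster`.
#'
#' @param slopeMap a [SlopeMap-class] (>= 5 subjects).
#' @param montage a [Montage-class] covering the slope-map channels.
#' @param nPerm number of sign-flip permutations.
#' @param clusterFormingP two-tailed point-wise p for the cluster-forming
#'   threshold.
#' @param alphaCluster cluster-level significance level.
#' @param seed RNG seed for the sign flips (recorded in the result).
#' @return a [ClusterResult-class]; an empty cluster list when no point
#'   exceeds the forming threshold.
#' @export
clusterPermutation <- function(slopeMap, montage, nPerm = 5000,
                               clusterFormingP = 0.01, alphaCluster = 0.01,
                               seed = 1L) {
  stopifnot(is(slopeMap, "SlopeMap"), is(montage, "Montage"))
  n <- length(slopeMap@subjects)
  stopIf(n < 5, "cluster permutation needs >= 5 subjects (unstable t below)")
  nCh <- length(slopeMap@channels); nTi <- length(slopeMap@times)
  X <- slopeMap@slopes
  dim(X) <- c(n, nCh * nTi)
  adj <- adjacencyList0(montage, slopeMap@channels)
  thr <- qt(1 - clusterFormingP / 2, df = n - 1)

  colSq <- colSums(X^2)
  tFromMean <- function(m) {
    v <- (colSq - n * m^2) / (n - 1)
    m / sqrt(pmax(v, .Machine$double.eps) / n)
  }
  tobs <- tFromMean(colMeans(X))
  obs <- .clLabel(tobs, nCh, nTi, thr, adj)

  nullMax <- withSeed(seed, {
    out <- numeric(nPerm)
    chunk <- 500L
    done <- 0L
    while (done < nPerm) {
      k <- min(chunk, nPerm - done)
      signs <- matrix(sample(c(-1, 1), k * n, replace = TRUE), k, n)
      tmat <- t(apply(signs %*% X / n, 1, tFromMean))
      if (k == 1) tmat <- matrix(tmat, nrow = 1)
      out[done + seq_len(k)] <-
        .clMaxMassBatch(tmat, nCh, nTi, thr, adj)
      done <- done + k
    }
    out
  })

  clusters <- lapply(seq_along(obs$masses), function(i) {
    members <- which(obs$labels == i, arr.ind = TRUE)
    colnames(members) <- c("channel", "time")
    list(id = i, sign = obs$signs[i], mass = obs$masses[i],
         p = (1 + sum(nullMax >= obs$masses[i])) / (1 + nPerm),
         members = members,
         channels = slopeMap@channels[unique(members[, 1])],
         times = range(slopeMap@times[members[, 2]]))
  })
  new("ClusterResult", clusters = clusters,
      tmap = matrix(tobs, nCh, nTi), labels = obs$labels,
      tThreshold = thr, clusterFormingP = clusterFormingP,
      alphaCluster = alphaCluster, nPerm = nPerm, seed = as.numeric(seed),
      nullMax = nullMax, channels = slopeMap@channels,
      times = slopeMap@times)
}

#' Retain significant points matching the behavioral slope CI
#'
#' The linking step: a point inside a significant cluster is retained iff
#' the cross-subject mean EEG slope at that point lies within the 95
#' percent confidence interval of the behavioral d-prime/log-jitter slope.
#' In `"cluster"` mode the decision is made per cluster from its average
#' slope instead (both readings of the retention rule are available).
#'
#' @param clusters a [ClusterResult-class].
#' @param slopeMap the [SlopeMap-class] the clusters were computed from.
#' @param behavioral the behavioral slope CI: a numeric `c(lo, hi)`, a
#'   [DprimeRegression-class], or a list/vector of per-subject slopes (see
#'   [behavioralSlopeCI()]).
#' @param mode `"point"` (default) or `"cluster"`.
#' @return a [MatchMask-class]; its mask is always a subset of the
#'   significant clusters.
#' @export
matchBehavioralCI <- function(clusters, slopeMap, behavioral,
                              mode = c("point", "cluster")) {
  stopifnot(is(clusters, "ClusterResult"), is(slopeMap, "SlopeMap"))
  mode <- match.arg(mode)
  stopIf(!identical(clusters@channels, slopeMap@channels) ||
           !isTRUE(all.equal(clusters@times, slopeMap@times)),
         "cluster result and slope map are on different grids")
  ci <- if (is.numeric(behavioral) && length(behavioral) == 2)
    sort(behavioral) else behavioralSlopeCI(behavioral)
  meanSlope <- apply(slopeMap@slopes, c(2, 3), mean)
  mask <- matrix(FALSE, length(clusters@channels), length(clusters@times))
  for (cl in clusters@clusters) {
    if (cl$p > clusters@alphaCluster) next
    if (mode == "point") {
      v <- meanSlope[cl$members]
      keep <- v >= ci[1] & v <= ci[2]
      mask[cl$members[keep, , drop = FALSE]] <- TRUE
    } else {
      avg <- mean(meanSlope[cl$members])
      if (avg >= ci[1] && avg <= ci[2]) mask[cl$members] <- TRUE
    }
  }
  new("MatchMask", mask = mask, ci = ci, mode = mode,
      channels = clusters@channels, times = clusters@times)
}

#' Re-epoch stimulus-locked data around the behavioral response
#'
#' Re-centers each trial's window on stimulus onset plus that trial's RT
#' (nearest sample).  Trials whose requested window exceeds the available
#' samples are dropped with a message; it is an error if no trial
#' survives.
#'
#' @param epochs a stimulus-locked [EpochSet-class] whose trial table has
#'   `rt_ms`.
#' @param windowMs response-locked window, default `c(-1000, 0)` ms.
#' @return a response-locked [EpochSet-class].
#' @export
relockToResponse <- function(epochs, windowMs = c(-1000, 0)) {
  stopifnot(is(epochs, "EpochSet"))
  tr <- epochs@trials
  stopIf(is.null(tr$rt_ms), "trial table lacks rt_ms")
  dt <- epochs@times[2] - epochs@times[1]
  nOut <- round((windowMs[2] - windowMs[1]) / dt) + 1L
  start <- round((tr$rt_ms + windowMs[1] - epochs@times[1]) / dt) + 1L
  ok <- start >= 1 & (start + nOut - 1L) <= length(epochs@times)
  if (any(!ok))
    message(sum(!ok), " trial(s) dropped: response window outside the epoch")
  stopIf(!any(ok), "no trial has enough samples for the response window")
  rows <- which(ok)
  d <- dim(epochs@data)
  out <- array(NA_real_, c(length(rows), d[2], nOut))
  for (i in seq_along(rows)) {
    s <- start[rows[i]]
    out[i, , ] <- epochs@data[rows[i], , s:(s + nOut - 1L)]
  }
  new("EpochSet", data = out,
      times = seq(windowMs[1], by = dt, length.out = nOut),
      lock = "response", channels = epochs@channels,
      trials = tr[rows, , drop = FALSE], units = epochs@units)
}
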