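## Per-timepoint shrinkage-LDA decoding of stimulus orientation: class
## balancing, oracle-approximating shrinkage estimation, stratified
## cross-validation, activation-pattern projection and temporal cluster
## inference on accuracy traces.

#' Balance two classes by down-sampling the majority class
#'
#' Uniform random removal of majority-class trials down to the minority
#' count; already balanced inputs pass through unchanged.  Seeded.
#'
#' @param trials trial table with the class column.
#' @param column class column name (default `"orientation"`).
#' @param seed RNG seed.
#' @return integer vector of retained row indices (sorted).
#' @export
balanceClasses <- function(trials, column = "orientation", seed = 1L) {
  lab <- trials[[column]]
  stopIf(is.null(lab), "column not found: ", column)
  cls <- unique(lab)
  stopIf(length(cls) != 2 || any(table(lab) == 0),
         "need exactly two non-empty classes")
  n <- table(lab)
  nMin <- min(n)
  idx <- withSeed(seed, unlist(lapply(cls, function(cl) {
    rows <- which(lab == cl)
    if (length(rows) > nMin) sort(sample(rows, nMin)) else rows
  })))
  sort(idx)
}

## Oracle-approximating shrinkage coefficient for one n x p data matrix
## (rows = trials).  Target: scaled identity (average eigenvalue).
oasGamma <- function(X) {
  n <- nrow(X); p <- ncol(X)
  stopIf(n < 2, "need >= 2 trials to estimate covariance")
  S <- stats::cov(X)
  trS <- sum(diag(S))
  trS2 <- sum(S * S)
  num <- (1 - 2 / p) * trS2 + trS^2
  den <- (n + 1 - 2 / p) * (trS2 - trS^2 / p)
  if (den <= 0) return(1)       # boundary: (near-)spherical or rank-deficient
  min(1, num / den)
}

#' Common shrinkage factor across subjects
#'
#' Computes the oracle-approximating shrinkage (OAS) coefficient of the
#' channel covariance at every timepoint, averages over timepoints within
#' subject, then over subjects, giving the single gamma used by
#' [decodeTimecourse()] for all subjects.
#'
#' @param epochsList list of [EpochSet-class] objects, one per subject (a
#'   single EpochSet is accepted).
#' @return scalar gamma in \[0, 1\].
#' @export
estimateCommonShrinkage <- function(epochsList) {
  if (is(epochsList, "EpochSet")) epochsList <- list(epochsList)
  stopIf(!length(epochsList), "need >= 1 subject")
  perSubj <- vapply(epochsList, function(ep) {
    stopifnot(is(ep, "EpochSet"))
    d <- dim(ep@data)
    stopIf(d[1] < 2, "fewer than 2 trials")
    mean(vapply(seq_len(d[3]), function(ti)
      oasGamma(ep@data[, , ti]), numeric(1)))
  }, numeric(1))
  mean(perSubj)
}

## Shrinkage-LDA weight vector for one training set: pooled within-class
## covariance shrunk toward the scaled identity, w = Sigma_gamma^{-1}
## (mu1 - mu0).  Returns list(w, b) with decision rule w'x > b -> class 1.
ldaTrain <- function(X, y, gamma) {
  cls <- sort(unique(y))
  X0 <- X[y == cls[1], , drop = FALSE]
  X1 <- X[y == cls[2], , drop = FALSE]
  m0 <- colMeans(X0); m1 <- colMeans(X1)
  n0 <- nrow(X0); n1 <- nrow(X1)
  S <- ((n0 - 1) * stats::cov(X0) + (n1 - 1) * stats::cov(X1)) /
    (n0 + n1 - 2)
  p <- ncol(X)
  Sg <- (1 - gamma) * S + gamma * (sum(diag(S)) / p) * diag(p)
  w <- drop(solve(Sg, m1 - m0))
  list(w = w, b = sum(w * (m0 + m1) / 2), classes = cls)
}

#' Stratified fold assignment
#'
#' Assigns trials to `nFolds` folds so that class proportions per fold
#' differ by at most one trial.  Seeded.
#'
#' @param y class labels.
#' @param nFolds number of folds.
#' @param seed RNG seed.
#' @return integer fold index per trial.
#' @export
stratifiedFolds <- function(y, nFolds = 10, seed = 1L) {
  withSeed(seed, {
    fold <- integer(length(y))
    start <- 0L   # rotate fold assignment so remainders spread evenly
    for (cl in unique(y)) {
      rows <- sample(which(y == cl))
      fold[rows] <- (seq_along(rows) - 1L + start) %% nFolds + 1L
      start <- start + length(rows)
    }
    fold
  })
}

#' Per-timepoint shrinkage-LDA decoding
#'
#' At each timepoint the channel vector is the feature set; a linear
#' discriminant with covariance \eqn{\Sigma_\gamma = (1-\gamma)\hat\Sigma +
#' \gamma\,(\mathrm{tr}\hat\Sigma/C)\,I} (pooled across classes) is trained
#' and evaluated under stratified k-fold cross-validation.  Weights and
#' activation patterns (covariance times weights, unit maximum absolute
#' value) come from the full-data fit at each timepoint.
#'
#' Classes must be balanced first (see [balanceClasses()]).
#'
#' @param epochs an [EpochSet-class] for one subject.
#' @param gamma shrinkage coefficient (see [estimateCommonShrinkage()]).
#' @param nFolds folds (default 10); must not exceed the minority count.
#' @param seed RNG seed for fold assignment.
#' @param column class column in the trial table.
#' @return a [DecodingResult-class].
#' @export
decodeTimecourse <- function(epochs, gamma, nFolds = 10, seed = 1L,
                             column = "orientation") {
  stopifnot(is(epochs, "EpochSet"))
  y <- epochs@trials[[column]]
  stopIf(is.null(y), "column not found: ", column)
  tab <- table(y)
  stopIf(length(tab) != 2, "need exactly two classes")
  stopIf(abs(diff(as.numeric(tab))) > 0,
         "classes are unbalanced; run balanceClasses() first")
  stopIf(min(tab) < nFolds, "nFolds exceeds the minority class count")
  d <- dim(epochs@data)
  stopIf(d[1] < 2 * nFolds, "need at least 2 trials per fold")
  fold <- stratifiedFolds(y, nFolds, seed)
  acc <- numeric(d[3])
  W <- matrix(0, d[2], d[3])
  P <- matrix(0, d[2], d[3])
  for (ti in seq_len(d[3])) {
    X <- epochs@data[, , ti]
    hits <- 0L
    for (f in seq_len(nFolds)) {
      tr <- fold != f
      mdl <- ldaTrain(X[tr, , drop = FALSE], y[tr], gamma)
      pred <- ifelse(drop(X[!tr, , drop = FALSE] %*% mdl$w) > mdl$b,
                     mdl$classes[2], mdl$classes[1])
      hits <- hits + sum(pred == y[!tr])
    }
    acc[ti] <- hits / d[1]
    mdl <- ldaTrain(X, y, gamma)
    W[, ti] <- mdl$w
    P[, ti] <- activationPatterns(mdl$w, stats::cov(X))
  }
  new("DecodingResult", accuracy = acc, weights = W, patterns = P,
      gamma = gamma, nFolds = nFolds, seed = as.numeric(seed),
      channels = epochs@channels, times = epochs@times)
}

#' Project classifier weights to an activation pattern
#'
#' The forward-model projection `pattern = covariance %*% weights`,
#' normalized to unit maximum absolute value; unlike raw weights, patterns
#' are interpretable as scalp topographies of the decoded signal.
#'
#' @param weights channel weight vector.
#' @param covariance channels x channels data covariance (symmetric PSD).
#' @return pattern vector, max |.| = 1 (all-zero weights give zeros).
#' @export
activationPatterns <- function(weights, covariance) {
  stopIf(length(weights) != nrow(covariance) ||
           nrow(covariance) != ncol(covariance),
         "dimension mismatch between weights and covariance")
  stopIf(max(abs(covariance - t(covariance))) > 1e-8 * max(1, max(abs(covariance))),
         "covariance must be symmetric")
  p <- drop(covariance %*% weights)
  m <- max(abs(p))
  if (m > 0) p / m else p
}

#' Temporal cluster test of decoding accuracy against chance
#'
#' One-sample t of per-subject accuracy against chance at every timepoint;
#' suprathreshold runs are clustered by temporal contiguity with consistent
#' sign and tested against the sign-flip permutation distribution of the
#' maximum cluster mass (same statistic and p convention as
#' [clusterPermutation()]).
#'
#' @param accuracy subjects x time matrix of decoding accuracies.
#' @param chance chance level (default 0.5).
#' @param nPerm permutations.
#' @param clusterFormingP,alphaCluster thresholds.
#' @param seed RNG seed.
#' @param times optional time axis for labeling.
#' @return a [ClusterResult-class] on a 1 x time grid collapsed to
#'   temporal clusters.
#' @export
temporalClusterTest <- function(accuracy, chance = 0.5, nPerm = 1000,
                                clusterFormingP = 0.05, alphaCluster = 0.05,
                                seed = 1L, times = NULL) {
  stopIf(!is.matrix(accuracy), "accuracy must be subjects x time")
  n <- nrow(accuracy)
  stopIf(n < 5, "temporal cluster test needs >= 5 subjects")
  X <- accuracy - chance
  nTi <- ncol(X)
  times <- times %||% seq_len(nTi)
  adj <- list(integer(0))                  # single channel: chain topology
  thr <- qt(1 - clusterFormingP / 2, df = n - 1)
  colSq <- colSums(X^2)
  tFromMean <- function(m) {
    v <- (colSq - n * m^2) / (n - 1)
    m / sqrt(pmax(v, .Machine$double.eps) / n)
  }
  tobs <- tFromMean(colMeans(X))
  obs <- .clLabel(tobs, 1L, nTi, thr, adj)
  nullMax <- withSeed(seed, {
    signs <- matrix(sample(c(-1, 1), nPerm * n, replace = TRUE), nPerm, n)
    tmat <- t(apply(signs %*% X / n, 1, tFromMean))
    if (nPerm == 1) tmat <- matrix(tmat, nrow = 1)
    .clMaxMassBatch(tmat, 1L, nTi, thr, adj)
  })
  clusters <- lapply(seq_along(obs$masses), function(i) {
    members <- which(obs$labels == i, arr.ind = TRUE)
    colnames(members) <- c("channel", "time")
    list(id = i, sign = obs$signs[i], mass = obs$masses[i],
         p = (1 + sum(nullMax >= obs$masses[i])) / (1 + nPerm),
         members = members, channels = "accuracy",
         times = range(times[members[, 2]]))
  })
  new("ClusterResult", clusters = clusters,
      tmap = matrix(tobs, 1L, nTi), labels = obs$labels, tThreshold = thr,
      clusterFormingP = clusterFormingP, alphaCluster = alphaCluster,
      nPerm = nPerm, seed = as.numeric(seed), nullMax = nullMax,
      channels = "accuracy", times = as.numeric(times))
}
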