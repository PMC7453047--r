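## Seeded synthetic-data generators: probit observers performing the
## constant-stimuli shape discrimination task, electrode montages, and
## epoched EEG with planted components, a planted rectified-amplitude /
## log-jitter dependence, and a stimulus-orientation class signal.

#' Specification of a synthetic observer and session schedule
#'
#' Bundles the probit observer model per condition, the lognormal RT model
#' (defaults target a mean near 820 ms), and the session schedule: blocks
#' of 432 trials equally divided across six jitter levels (72 repetitions
#' per level per block), two blocks per condition.
#'
#' @param conditions condition labels.
#' @param probit named list (per condition) of lists with `mu`, `scale`,
#'   `guess`, `lapse`; a single list is recycled to all conditions.
#' @param blocksPerCondition,trialsPerBlock schedule counts;
#'   `trialsPerBlock` must divide evenly over the jitter levels, and the
#'   per-level count must be even so stimulus orientation can be balanced.
#' @param jitterLevels jitter SD ladder, degrees.
#' @param rtMeanlog,rtSdlog lognormal RT parameters (ms scale).
#' @param isiMs inter-stimulus interval set, ms.
#' @return a list of class `ObserverSpec`.
#' @examples
#' spec <- observerSpec()
#' spec$trialsPerBlock / length(spec$jitterLevels)  # 72 repetitions
#' @export
observerSpec <- function(conditions = c("contour_fixed", "surface_fixed"),
                         probit = list(mu = 40, scale = 12, guess = 0.5,
                                       lapse = 0.02),
                         blocksPerCondition = 2, trialsPerBlock = 432,
                         jitterLevels = veplink::jitterLevels(),
                         rtMeanlog = log(820) - 0.144^2 / 2,
                         rtSdlog = 0.144,
                         isiMs = c(500, 550, 600, 650)) {
  if (!is.list(probit[[1]])) probit <- setNames(
    rep(list(probit), length(conditions)), conditions)
  stopIf(!all(conditions %in% names(probit)),
         "probit must be given for every condition")
  perLevel <- trialsPerBlock / length(jitterLevels)
  stopIf(perLevel != round(perLevel),
         "trialsPerBlock must divide evenly across jitter levels")
  stopIf(perLevel %% 2 != 0,
         "per-level trial count must be even to balance orientation")
  structure(list(conditions = conditions, probit = probit,
                 blocksPerCondition = blocksPerCondition,
                 trialsPerBlock = trialsPerBlock,
                 jitterLevels = jitterLevels, rtMeanlog = rtMeanlog,
                 rtSdlog = rtSdlog, isiMs = isiMs),
            class = "ObserverSpec")
}

#' Simulate a behavioral session
#'
#' Draws one full constant-stimuli session for one observer: per trial a
#' balanced stimulus orientation, a Bernoulli correctness with probability
#' given by the condition's probit function at the trial's jitter level, the
#' response implied by orientation and correctness, a lognormal RT and an
#' ISI drawn from the configured set.  Levels are shuffled within block.
#' Identical seeds give identical tables.
#'
#' @param spec an [observerSpec()].
#' @param seed integer RNG seed.
#' @param subject subject label written into the table.
#' @return `data.frame` with columns `subject`, `condition`, `block`,
#'   `trial`, `jitter_deg`, `orientation`, `response`, `correct`, `rt_ms`,
#'   `isi_ms`.
#' @export
simulateBehavior <- function(spec, seed = 1L, subject = "S01") {
  stopifnot(inherits(spec, "ObserverSpec"))
  withSeed(seed, {
    perLevel <- spec$trialsPerBlock / length(spec$jitterLevels)
    out <- list()
    for (cond in spec$conditions) {
      pr <- spec$probit[[cond]]
      pars <- c(pr$mu, pr$scale, pr$guess, pr$lapse)
      for (b in seq_len(spec$blocksPerCondition)) {
        jit <- rep(spec$jitterLevels, each = perLevel)
        ori <- rep(rep(c("vertical", "horizontal"), each = perLevel / 2),
                   times = length(spec$jitterLevels))
        ord <- sample(length(jit))
        jit <- jit[ord]; ori <- ori[ord]
        p <- evaluateProbit(pars, jit)
        correct <- rbinom(length(jit), 1, p) == 1
        response <- ifelse(correct, ori,
                           ifelse(ori == "vertical", "horizontal",
                                  "vertical"))
        out[[length(out) + 1L]] <- data.frame(
          subject = subject, condition = cond, block = b,
          trial = seq_along(jit), jitter_deg = jit, orientation = ori,
          response = response, correct = correct,
          rt_ms = rlnorm(length(jit), spec$rtMeanlog, spec$rtSdlog),
          isi_ms = sample(spec$isiMs, length(jit), replace = TRUE))
      }
    }
    do.call(rbind, out)
  })
}

#' Build a synthetic electrode montage
#'
#' Channels are laid out on the upper unit hemisphere along a Fibonacci
#' spiral (near-uniform coverage).  Adjacency links channels closer than a
#' distance threshold; the default threshold is the median distance to the
#' 6th-nearest neighbor, which keeps the median neighbor count in the 4-10
#' range typical of sensor-space cluster tests.
#'
#' @param nChannels number of channels (>= 2).
#' @param threshold adjacency distance threshold; `NULL` for the default
#'   rule above.
#' @return a [Montage-class].  Errors if any channel ends up isolated
#'   (e.g. a degenerate threshold near 0).
#' @examples
#' mon <- makeMontage(32)
#' @export
makeMontage <- function(nChannels = 128, threshold = NULL) {
  stopIf(nChannels < 2, "need >= 2 channels")
  i <- seq_len(nChannels)
  z <- (i - 0.5) / nChannels
  r <- sqrt(pmax(0, 1 - z^2))
  golden <- pi * (3 - sqrt(5))
  pos <- cbind(x = r * cos(i * golden), y = r * sin(i * golden), z = z)
  D <- as.matrix(dist(pos))
  if (is.null(threshold)) {
    k <- min(6L, nChannels - 1L)
    d6 <- apply(D, 1, function(d) sort(d)[k + 1L])
    threshold <- median(d6)
  }
  adj <- D < threshold
  diag(adj) <- FALSE
  dimnames(adj) <- NULL
  new("Montage", channels = sprintf("E%03d", i), positions = pos,
      adjacency = adj, threshold = threshold)
}

#' Adjacency matrix of a montage
#' @param montage a [Montage-class].
#' @return logical channels x channels matrix.
#' @export
adjacencyMatrix <- function(montage) {
  stopifnot(is(montage, "Montage"))
  montage@adjacency
}

#' Specification of a synthetic EEG recording
#'
#' Describes the generative model for [simulateEpochs()].  Epochs are the
#' sum of (i) spatially correlated Gaussian noise (exponential kernel on
#' inter-electrode distance) plus white sensor noise, (ii) evoked
#' components -- a zero-sum topography times a Gaussian time kernel, with a
#' per-subject latency offset drawn once per subject, (iii) a planted
#' effect adding `amplitude + slope * log(jitter)` times a zero-sum
#' topography inside a time window, and (iv) a class signal whose sign
#' follows the stimulus orientation.  Component, effect and class-signal
#' amplitudes are stated in post-preprocessing z-units: the generator
#' rescales the clean signal so that after average-referencing and pooled
#' z-scoring the planted values are recovered (zero-sum topographies make
#' average-referencing exact on the planted signal).
#'
#' Defaults emulate a 128-channel, 200-Hz recording spanning -1000 to
#' +1000 ms with evoked components near 90, 307 and 402 ms (cross-subject
#' latency SDs 11.1, 10.9, 27.9 ms), a negative rectified-amplitude /
#' log-jitter slope at 10 electrodes in 380-440 ms, and an
#' orientation-dependent topography in 320-445 ms.
#'
#' @param nChannels,fsHz,windowMs recording geometry.
#' @param sigmaSpatial,sigmaWhite,lambda noise model: SD of the spatially
#'   correlated process, SD of white noise, kernel length (unit-sphere
#'   chord distance).
#' @param components list of component descriptors (`label`, `latencyMs`,
#'   `latencySdMs`, `widthMs`, `amplitude`, optional `topography`).
#' @param effect `NULL` or list(`channels`, `windowMs`, `slope`,
#'   `amplitude`): the planted jitter effect.
#' @param classSignal `NULL` or list(`channels`, `windowMs`, `amplitude`).
#' @param calibrationWindowMs the analysis window whose pooled z-scale
#'   defines the planted units (the z-scoring pool depends on the epoch
#'   crop, so planted values are recovered exactly when preprocessing is
#'   applied to this window).
#' @param seed base seed for topography generation.
#' @return a list of class `EEGSpec`.
#' @export
eegSpec <- function(nChannels = 128, fsHz = 200,
                    windowMs = c(-1000, 1000),
                    sigmaSpatial = 0.8, sigmaWhite = 0.6, lambda = 0.5,
                    components = list(
                      list(label = "C90", latencyMs = 90, latencySdMs = 11.1,
                           widthMs = 20, amplitude = 1.2),
                      list(label = "C307", latencyMs = 307,
                           latencySdMs = 10.9, widthMs = 35, amplitude = 1.5),
                      list(label = "C402", latencyMs = 402,
                           latencySdMs = 27.9, widthMs = 45,
                           amplitude = 1.2)),
                    effect = list(channels = NULL, windowMs = c(380, 440),
                                  slope = -0.18, amplitude = 3),
                    classSignal = list(channels = NULL,
                                       windowMs = c(320, 445),
                                       amplitude = 0.8),
                    calibrationWindowMs = c(-100, 500),
                    seed = 99L) {
  stopIf(windowMs[2] <= windowMs[1], "invalid epoch window")
  for (cmp in components)
    stopIf(cmp$latencyMs < windowMs[1] || cmp$latencyMs > windowMs[2],
           "component latency outside the epoch window: ", cmp$label)
  for (blk in list(effect, classSignal)) if (!is.null(blk))
    stopIf(blk$windowMs[1] < windowMs[1] || blk$windowMs[2] > windowMs[2],
           "planted window outside the epoch window")
  calibrationWindowMs <- c(max(calibrationWindowMs[1], windowMs[1]),
                           min(calibrationWindowMs[2], windowMs[2]))
  structure(list(nChannels = nChannels, fsHz = fsHz, windowMs = windowMs,
                 sigmaSpatial = sigmaSpatial, sigmaWhite = sigmaWhite,
                 lambda = lambda, components = components, effect = effect,
                 classSignal = classSignal,
                 calibrationWindowMs = calibrationWindowMs, seed = seed),
            class = "EEGSpec")
}

## Zero-sum topography supported on `channels`: alternating +1/-1 signs so
## that average-referencing leaves the planted signal untouched.
zeroSumSigns <- function(channels) {
  s <- rep(c(1, -1), length.out = length(channels))
  if (length(channels) %% 2 == 1) s <- s - mean(s)
  s
}

## Smooth random zero-mean topography over all channels, unit max |.|.
smoothTopography <- function(montage, lambda, seed) {
  D <- as.matrix(dist(montage@positions))
  K <- exp(-D / lambda)
  R <- chol(K + diag(1e-8, nrow(K)))
  w <- withSeed(seed, drop(crossprod(R, rnorm(nrow(K)))))
  w <- w - mean(w)
  w / max(abs(w))
}

#' Simulate epoched EEG for one or more subjects
#'
#' Generates an [EpochSet-class] realizing the model of [eegSpec()] for the
#' trials of `behavior` (one subject per distinct `subject` value;
#' per-subject component latency offsets are drawn once per subject from a
#' subject-keyed stream).  The planted parameters are returned in a
#' ground-truth sidecar intended only for recovery tests.
#'
#' @param spec an [eegSpec()].
#' @param behavior behavioral trial table (needs `jitter_deg`,
#'   `orientation`, `rt_ms`, `subject`).
#' @param montage a [Montage-class] with `spec$nChannels` channels.
#' @param seed integer RNG seed.
#' @return list with elements `epochs` (an [EpochSet-class], units
#'   `"sim"`) and `truth` (list: `effectMask` logical channels x time,
#'   `effectSlope`, `effectAmplitude`, `effectChannels`, `classChannels`,
#'   `classMask`, `scale`, `latencyOffsets`, `componentTopographies`).
#' @export
simulateEpochs <- function(spec, behavior, montage, seed = 1L) {
  stopifnot(inherits(spec, "EEGSpec"), is(montage, "Montage"))
  stopIf(nrow(behavior) == 0, "behavior table is empty")
  stopIf(length(montage@channels) != spec$nChannels,
         "montage does not match spec$nChannels")
  need <- c("jitter_deg", "orientation", "rt_ms", "subject")
  stopIf(!all(need %in% names(behavior)),
         "behavior table needs columns ", paste(need, collapse = ", "))

  nCh <- spec$nChannels
  times <- seq(spec$windowMs[1], spec$windowMs[2], by = 1000 / spec$fsHz)
  nT <- length(times)
  nTr <- nrow(behavior)
  subjects <- unique(behavior$subject)

  ## default planted channel sets: spread over the montage
  pick <- function(n, from = seq_len(nCh))
    from[round(seq(1, length(from), length.out = n))]
  effect <- spec$effect
  if (!is.null(effect) && is.null(effect$channels))
    effect$channels <- pick(min(10L, nCh))
  classSignal <- spec$classSignal
  if (!is.null(classSignal) && is.null(classSignal$channels)) {
    avail <- if (is.null(effect)) seq_len(nCh)
             else setdiff(seq_len(nCh), effect$channels)
    classSignal$channels <- pick(min(8L, length(avail)), from = avail)
  }

  compTopo <- lapply(seq_along(spec$components), function(k)
    smoothTopography(montage, spec$lambda, childSeed(spec$seed, k)))

  ## per-subject latency offsets, one draw per subject per component
  latOff <- lapply(subjects, function(s) {
    chars <- utf8ToInt(as.character(s))
    key <- sum(chars * seq_along(chars)) %% 100000L
    withSeed(childSeed(spec$seed, 1000L + key),
             vapply(spec$components, function(cmp)
               rnorm(1, 0, cmp$latencySdMs), numeric(1)))
  })
  names(latOff) <- subjects

  ## clean signal in z-units, trials x channels x time
  g <- array(0, dim = c(nTr, nCh, nT))
  logj <- log(behavior$jitter_deg)
  oriSign <- ifelse(behavior$orientation == "vertical", 1, -1)
  subjIdx <- match(behavior$subject, subjects)

  for (k in seq_along(spec$components)) {
    cmp <- spec$components[[k]]
    topo <- cmp$topography %||% compTopo[[k]]
    for (si in seq_along(subjects)) {
      rows <- which(subjIdx == si)
      kern <- cmp$amplitude *
        exp(-(times - cmp$latencyMs - latOff[[si]][k])^2 /
              (2 * cmp$widthMs^2))
      g[rows, , ] <- g[rows, , , drop = FALSE] +
        rep(1, length(rows)) %o% topo %o% kern
    }
  }

  effectMask <- matrix(FALSE, nCh, nT)
  if (!is.null(effect)) {
    tin <- times >= effect$windowMs[1] & times <= effect$windowMs[2]
    effectMask[effect$channels, tin] <- TRUE
    signs <- zeroSumSigns(effect$channels)
    m <- effect$amplitude + effect$slope * logj     # per-trial magnitude
    g[, effect$channels, tin] <- g[, effect$channels, tin, drop = FALSE] +
      m %o% signs %o% rep(1, sum(tin))
  }

  classMask <- matrix(FALSE, nCh, nT)
  if (!is.null(classSignal)) {
    tin <- times >= classSignal$windowMs[1] & times <= classSignal$windowMs[2]
    classMask[classSignal$channels, tin] <- TRUE
    signs <- zeroSumSigns(classSignal$channels)
    g[, classSignal$channels, tin] <-
      g[, classSignal$channels, tin, drop = FALSE] +
      (oriSign * classSignal$amplitude) %o% signs %o% rep(1, sum(tin))
  }

  calib <- times >= spec$calibrationWindowMs[1] &
    times <= spec$calibrationWindowMs[2]
  gw <- g[, , calib, drop = FALSE]
  vClean <- mean((gw - mean(gw))^2)
  stopIf(vClean >= 0.9, "planted signal variance too large (", round(vClean, 3),
         "); reduce amplitudes or enlarge the epoch")
  D <- as.matrix(dist(montage@positions))
  K <- spec$sigmaSpatial^2 * exp(-D / spec$lambda) +
    diag(spec$sigmaWhite^2, nCh)
  ## calibration uses the post-average-reference noise variance, so that
  ## the standard preprocessing chain (reference, pooled z-score) returns
  ## the planted amplitudes exactly (zero-sum topographies pass the
  ## reference untouched)
  C <- diag(nCh) - 1 / nCh
  sigmaRef <- sqrt(mean(diag(C %*% K %*% C)))
  S <- sigmaRef / sqrt(1 - vClean)
  R <- chol(K)
  noise <- withSeed(seed, {
    z <- matrix(rnorm(nTr * nT * nCh), nTr * nT, nCh)
    array(z %*% R, dim = c(nTr, nT, nCh))
  })
  data <- g * S + aperm(noise, c(1, 3, 2))

  epochs <- new("EpochSet", data = data, times = times, lock = "stimulus",
                channels = montage@channels, trials = behavior,
                units = "sim")
  truth <- list(effectMask = effectMask,
                effectSlope = if (is.null(effect)) NULL else effect$slope,
                effectAmplitude = if (is.null(effect)) NULL
                  else effect$amplitude,
                effectChannels = if (is.null(effect)) integer(0)
                  else effect$channels,
                classChannels = if (is.null(classSignal)) integer(0)
                  else classSignal$channels,
                classMask = classMask, scale = S, times = times,
                latencyOffsets = latOff,
                componentTopographies = compTopo, seed = seed)
  list(epochs = epochs, truth = truth)
}
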