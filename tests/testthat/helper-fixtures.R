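# Small in-code fixture builders shared across the test files.

# EpochSet straight from an array (channels auto-named).
makeEpochs <- function(data, times = NULL, trials = NULL, lock = "stimulus",
                       units = "sim") {
  d <- dim(data)
  times <- times %||% seq(0, by = 5, length.out = d[3])
  trials <- trials %||% data.frame(jitter_deg = rep(1, d[1]),
                                   subject = "S01")
  new("EpochSet", data = data, times = times, lock = lock,
      channels = sprintf("E%03d", seq_len(d[2])), trials = trials,
      units = units)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Gaussian-noise EpochSet with a jitter ladder in the trial table.
noiseEpochs <- function(nTrials, nCh, nT, seed = 1, subject = "S01") {
  set.seed(seed)
  trials <- data.frame(
    jitter_deg = rep(jitterLevels(), length.out = nTrials),
    orientation = rep(c("vertical", "horizontal"), length.out = nTrials),
    condition = "contour_fixed",
    rt_ms = stats::rlnorm(nTrials, log(820), 0.144),
    subject = subject)
  makeEpochs(array(rnorm(nTrials * nCh * nT), c(nTrials, nCh, nT)),
             trials = trials)
}

# Per-subject slope maps: white noise plus an optional planted block.
makeSlopeMaps <- function(nSubj = 16, nCh = 32, nT = 60, noiseSd = 0.3,
                          block = NULL, shift = 0, seed = 1) {
  set.seed(seed)
  arr <- array(rnorm(nSubj * nCh * nT, 0, noiseSd), c(nSubj, nCh, nT))
  if (!is.null(block))
    arr[, block$channels, block$times] <-
      arr[, block$channels, block$times, drop = FALSE] + shift
  new("SlopeMap", slopes = arr, subjects = sprintf("S%02d", seq_len(nSubj)),
      channels = sprintf("E%03d", seq_len(nCh)),
      times = seq(0, by = 5, length.out = nT), predictor = "log_jitter")
}

# Brute-force mean 4-nearest-neighbor distances (independent of the
# package's implementation).
bruteNN4 <- function(x, y, group = NULL) {
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    d <- sqrt((x - x[i])^2 + (y - y[i])^2)
    d[i] <- Inf
    if (!is.null(group)) d[group != group[i]] <- Inf
    out[i] <- mean(sort(d)[1:4])
  }
  out
}

subsetEpochs <- function(ep, rows) {
  new("EpochSet", data = ep@data[rows, , , drop = FALSE], times = ep@times,
      lock = ep@lock, channels = ep@channels,
      trials = ep@trials[rows, , drop = FALSE], units = ep@units)
}
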