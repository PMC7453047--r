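test_that("preprocessing stages satisfy their defining identities", {
  ep <- noiseEpochs(20, 8, 30, seed = 1)
  ref <- preprocessEpochs(ep, zscore = FALSE, rectify = FALSE)
  # average reference: cross-channel mean vanishes at every trial/timepoint
  m <- apply(epochData(ref), c(1, 3), mean)
  expect_lt(max(abs(m)), 1e-12)
  # z-scoring: pooled mean 0, SD 1 per subject
  z <- preprocessEpochs(ep, reference = FALSE, rectify = FALSE)
  expect_lt(abs(mean(epochData(z))), 1e-12)
  expect_equal(sd(epochData(z)), 1, tolerance = 1e-12)
  expect_identical(z@units, "z")
  # rectification: nonnegative and idempotent
  r <- preprocessEpochs(ep)
  expect_true(all(epochData(r) >= 0))
  r2 <- preprocessEpochs(r, reference = FALSE, zscore = FALSE)
  expect_identical(epochData(r2), epochData(r))
  # z-scoring is per subject when several subjects share the container
  tr2 <- ep@trials; tr2$subject <- rep(c("A", "B"), each = 10)
  ep2 <- new("EpochSet", data = ep@data * rep(c(1, 5), each = 10),
             times = ep@times, lock = "stimulus", channels = ep@channels,
             trials = tr2, units = "sim")
  z2 <- preprocessEpochs(ep2, reference = FALSE, rectify = FALSE)
  expect_equal(sd(epochData(z2)[1:10, , ]), 1, tolerance = 1e-12)
  expect_equal(sd(epochData(z2)[11:20, , ]), 1, tolerance = 1e-12)
  # degenerate input
  flat <- makeEpochs(array(1, c(4, 3, 5)))
  expect_error(preprocessEpochs(flat), "variance")
})

test_that("slope maps are exact on linear data and match per-point OLS", {
  nTr <- 60
  j <- rep(jitterLevels(), each = 10)
  amp <- 2 - 0.3 * log(j)
  data <- array(rep(amp, 5 * 8), c(nTr, 5, 8))
  ep <- makeEpochs(data, trials = data.frame(jitter_deg = j,
                                             subject = "S01"))
  sm <- fitSlopeMap(ep)
  expect_equal(as.vector(slopeArray(sm)), rep(-0.3, 40),
               tolerance = 1e-12)
  # vectorized slopes equal loop-computed lm() on a noisy 5-channel fixture
  set.seed(3)
  noisy <- data + array(rnorm(length(data)), dim(data))
  epn <- makeEpochs(noisy, trials = ep@trials)
  smn <- fitSlopeMap(epn)
  for (ch in 1:5) for (ti in c(1, 4, 8)) {
    b <- unname(coef(lm(noisy[, ch, ti] ~ log(j)))[2])
    expect_equal(slopeArray(smn)[1, ch, ti], b, tolerance = 1e-10)
  }
  # raw-jitter predictor mode
  smr <- fitSlopeMap(epn, predictor = "jitter")
  b <- unname(coef(lm(noisy[, 2, 3] ~ j))[2])
  expect_equal(slopeArray(smr)[1, 2, 3], b, tolerance = 1e-10)
  # level-means mode agrees with lm on the level averages
  sml <- fitSlopeMap(epn, levelMeans = TRUE)
  lev <- jitterLevels()
  ym <- vapply(lev, function(l) mean(noisy[j == l, 2, 3]), numeric(1))
  expect_equal(slopeArray(sml)[1, 2, 3],
               unname(coef(lm(ym ~ log(lev)))[2]), tolerance = 1e-10)
  # single jitter level is refused
  ep1 <- makeEpochs(data[1:10, , , drop = FALSE],
                    trials = data.frame(jitter_deg = rep(1, 10),
                                        subject = "S01"))
  expect_error(fitSlopeMap(ep1), "distinct jitter")
})

test_that("pure-noise slope maps concentrate on zero as trials grow", {
  res <- vapply(c(60, 600), function(n) {
    j <- rep(jitterLevels(), each = n / 6)
    set.seed(n)
    ep <- makeEpochs(array(rnorm(n * 4 * 6), c(n, 4, 6)),
                     trials = data.frame(jitter_deg = j, subject = "S01"))
    mean(abs(slopeArray(fitSlopeMap(ep))))
  }, numeric(1))
  expect_lt(res[2], res[1])
  expect_lt(res[2], 0.05)
})

test_that("cluster permutation recovers a planted block and nothing under null", {
  mon <- makeMontage(32)
  # all-zero maps: no suprathreshold point, empty result
  zero <- makeSlopeMaps(8, 32, 20, noiseSd = 0)
  zero@slopes[] <- 0
  cl0 <- clusterPermutation(zero, mon, nPerm = 50, seed = 1)
  expect_length(cl0@clusters, 0)
  expect_equal(nrow(clusterTable(cl0)), 0)
  # planted block: adjacent channels x contiguous samples
  block <- list(channels = 10:17, times = 21:32)
  sm <- makeSlopeMaps(16, 32, 60, noiseSd = 0.3, block = block,
                      shift = -0.5, seed = 2)
  cl <- clusterPermutation(sm, mon, nPerm = 400, seed = 3)
  tab <- clusterTable(cl)
  sig <- tab[tab$significant, ]
  expect_gte(nrow(sig), 1)
  expect_true(all(sig$sign == -1))
  expect_true(all(sig$p <= 0.01))
  hit <- matrix(FALSE, 32, 60)
  for (cc in cl@clusters) if (cc$p <= cl@alphaCluster) hit[cc$members] <- TRUE
  truth <- matrix(FALSE, 32, 60); truth[block$channels, block$times] <- TRUE
  jac <- sum(hit & truth) / sum(hit | truth)
  expect_gte(jac, 0.8)
  # subject floor is enforced
  expect_error(clusterPermutation(makeSlopeMaps(4, 32, 10), mon, 10),
               ">= 5 subjects")
})

test_that("cluster inference is equivariant to channel relabeling", {
  mon <- makeMontage(16)
  sm <- makeSlopeMaps(12, 16, 30, noiseSd = 0.3,
                      block = list(channels = 4:9, times = 10:20),
                      shift = -0.5, seed = 5)
  cl <- clusterPermutation(sm, mon, nPerm = 200, seed = 7)
  perm <- sample(16)
  mon2 <- new("Montage", channels = mon@channels[perm],
              positions = mon@positions[perm, ],
              adjacency = mon@adjacency[perm, perm],
              threshold = mon@threshold)
  sm2 <- new("SlopeMap", slopes = sm@slopes[, perm, , drop = FALSE],
             subjects = sm@subjects, channels = sm@channels[perm],
             times = sm@times, predictor = sm@predictor)
  cl2 <- clusterPermutation(sm2, mon2, nPerm = 200, seed = 7)
  t1 <- clusterTable(cl); t2 <- clusterTable(cl2)
  o1 <- order(t1$mass); o2 <- order(t2$mass)
  expect_equal(t1$mass[o1], t2$mass[o2], tolerance = 1e-9)
  expect_equal(t1$p[o1], t2$p[o2])
  expect_equal(t1$n_points[o1], t2$n_points[o2])
})

test_that("observed clusters do not depend on the number of permutations", {
  mon <- makeMontage(16)
  sm <- makeSlopeMaps(10, 16, 30, noiseSd = 0.4,
                      block = list(channels = 2:5, times = 5:12),
                      shift = -0.6, seed = 9)
  cl1 <- clusterPermutation(sm, mon, nPerm = 100, seed = 1)
  cl2 <- clusterPermutation(sm, mon, nPerm = 200, seed = 1)
  expect_identical(cl1@labels, cl2@labels)
  expect_equal(vapply(cl1@clusters, `[[`, numeric(1), "mass"),
               vapply(cl2@clusters, `[[`, numeric(1), "mass"))
})

test_that("sign-flip null keeps the family-wise error near its nominal level", {
  # light calibration run; the full-scale one lives in the acceptance suite
  mon <- makeMontage(16)
  fwe <- vapply(1:60, function(r) {
    sm <- makeSlopeMaps(12, 16, 30, noiseSd = 1, seed = 100 + r)
    cl <- clusterPermutation(sm, mon, nPerm = 200,
                             clusterFormingP = 0.05, alphaCluster = 0.05,
                             seed = r)
    any(clusterTable(cl)$significant)
  }, logical(1))
  # 99% binomial band around 0.05 for n = 60 is roughly [0, 0.12]
  expect_lte(mean(fwe), 0.13)
})

test_that("behavioral-CI matching retains exactly the points inside the band", {
  mon <- makeMontage(16)
  block <- list(channels = 4:9, times = 10:20)
  sm <- makeSlopeMaps(16, 16, 30, noiseSd = 0.05, block = block,
                      shift = -0.19, seed = 11)
  cl <- clusterPermutation(sm, mon, nPerm = 300, seed = 2)
  # CI matching the planted slope retains the cluster points
  mk <- matchBehavioralCI(cl, sm, c(-0.28, -0.10))
  truth <- matrix(FALSE, 16, 30); truth[block$channels, block$times] <- TRUE
  expect_gte(sum(maskMatrix(mk) & truth) / sum(truth), 0.8)
  # a CI excluding the slope empties the mask; containment always holds
  mk2 <- matchBehavioralCI(cl, sm, c(0.10, 0.28))
  expect_equal(sum(maskMatrix(mk2)), 0)
  sig <- matrix(FALSE, 16, 30)
  for (cc in cl@clusters) if (cc$p <= cl@alphaCluster) sig[cc$members] <- TRUE
  expect_true(all(sig[maskMatrix(mk)]))
  # cluster-average mode gives all-or-nothing retention per cluster
  mkc <- matchBehavioralCI(cl, sm, c(-0.28, -0.10), mode = "cluster")
  expect_true(all(maskMatrix(mkc)[truth] ==
                    maskMatrix(mkc)[truth][1]))
  # grid mismatch is an error
  smX <- makeSlopeMaps(16, 16, 29, seed = 1)
  expect_error(matchBehavioralCI(cl, smX, c(-1, 1)), "grids")
})

test_that("response-locked re-epoching shifts windows by the trial RT", {
  nTr <- 12; nCh <- 4
  times <- seq(-1000, 1000, by = 5)
  data <- array(rnorm(nTr * nCh * length(times)),
                c(nTr, nCh, length(times)))
  # rt = 0: the response-locked window equals the stimulus-locked crop
  tr0 <- data.frame(jitter_deg = 10, rt_ms = 0, subject = "S01")
  ep0 <- makeEpochs(data, times = times, trials = tr0[rep(1, nTr), ])
  rl0 <- relockToResponse(ep0, c(-1000, 0))
  keep <- times >= -1000 & times <= 0
  expect_equal(epochData(rl0), epochData(ep0)[, , keep, drop = FALSE])
  expect_identical(rl0@lock, "response")
  expect_equal(rl0@times, seq(-1000, 0, by = 5))
  # a spike at a fixed pre-response latency is aligned only after relock
  set.seed(4)
  rts <- round(runif(nTr, 400, 900) / 5) * 5
  data2 <- array(0, c(nTr, nCh, length(times)))
  for (i in seq_len(nTr))
    data2[i, , which(times == rts[i] - 200)] <- 7   # 200 ms before response
  ep2 <- makeEpochs(data2, times = times,
                    trials = data.frame(jitter_deg = 10, rt_ms = rts,
                                        subject = "S01"))
  rl2 <- relockToResponse(ep2, c(-1000, 0))
  peaks <- apply(epochData(rl2)[, 1, ], 1, which.max)
  expect_true(all(rl2@times[peaks] == -200))
  stimPeaks <- apply(data2[, 1, ], 1, which.max)
  expect_gt(sd(times[stimPeaks]), 0)
  # trials whose window leaves the epoch are dropped with a message
  tr3 <- data.frame(jitter_deg = 10, rt_ms = c(rep(500, 10), 5000, 5000),
                    subject = "S01")
  ep3 <- makeEpochs(data, times = times, trials = tr3)
  expect_message(rl3 <- relockToResponse(ep3, c(-1000, 0)), "2 trial")
  expect_equal(nTrials(rl3), 10)
  tr4 <- tr3; tr4$rt_ms <- 5000
  expect_error(suppressMessages(
    relockToResponse(makeEpochs(data, times = times, trials = tr4),
                     c(-1000, 0))), "no trial")
})
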