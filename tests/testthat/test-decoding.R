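# Independent implementation of the oracle-approximating shrinkage
# coefficient (Chen et al. form with the scaled-identity target).
oasOracle <- function(X) {
  n <- nrow(X); p <- ncol(X)
  S <- cov(X)
  trS <- sum(diag(S)); trS2 <- sum(S * S)
  num <- (1 - 2 / p) * trS2 + trS^2
  den <- (n + 1 - 2 / p) * (trS2 - trS^2 / p)
  if (den <= 0) 1 else min(1, num / den)
}

classEpochs <- function(nTr = 120, nCh = 10, nT = 30, amp = 1.5,
                        window = 11:20, seed = 1) {
  set.seed(seed)
  ori <- rep(c("vertical", "horizontal"), length.out = nTr)
  topo <- rep(c(1, -1), length.out = nCh) * c(rep(1, 4), rep(0, nCh - 4))
  data <- array(rnorm(nTr * nCh * nT), c(nTr, nCh, nT))
  sgn <- ifelse(ori == "vertical", 1, -1)
  data[, , window] <- data[, , window, drop = FALSE] +
    (sgn * amp) %o% topo %o% rep(1, length(window))
  list(epochs = makeEpochs(data,
                           trials = data.frame(jitter_deg = 10,
                                               orientation = ori,
                                               subject = "S01")),
       topo = topo)
}

test_that("class balancing down-samples the majority class only", {
  tr <- data.frame(orientation = rep(c("vertical", "horizontal"),
                                     c(100, 60)))
  idx <- balanceClasses(tr, seed = 3)
  expect_equal(unname(table(tr$orientation[idx])), c(60L, 60L),
               ignore_attr = TRUE)
  removed <- setdiff(seq_len(160), idx)
  expect_true(all(tr$orientation[removed] == "vertical"))
  # already balanced: identity
  tr2 <- data.frame(orientation = rep(c("vertical", "horizontal"), 30))
  expect_identical(balanceClasses(tr2, seed = 1), seq_len(60))
  # determinism
  expect_identical(balanceClasses(tr, seed = 3), idx)
  expect_false(identical(balanceClasses(tr, seed = 4), idx))
  expect_error(balanceClasses(data.frame(orientation = rep("v", 5))),
               "two non-empty")
})

test_that("shrinkage estimation matches the OAS formula across regimes", {
  set.seed(6)
  # trials >> channels with a well-conditioned, non-spherical covariance:
  # little shrinkage needed, gamma near 0
  Xbig <- matrix(rnorm(4000 * 8), 4000, 8) %*% diag(seq(0.5, 3, len = 8))
  expect_lt(oasOracle(Xbig), 0.01)
  # trials < channels: substantial shrinkage
  Xsmall <- matrix(rnorm(12 * 24), 12, 24)
  expect_gt(oasOracle(Xsmall), 0.3)
  # rank-1 replicated trials: boundary value without numerical failure
  Xrank1 <- matrix(rep(rnorm(6), each = 10), 10, 6)
  expect_equal(oasOracle(Xrank1), 1)
  # package estimator equals the direct formula averaged over timepoints
  ep <- makeEpochs(array(rnorm(40 * 6 * 5), c(40, 6, 5)))
  g <- estimateCommonShrinkage(ep)
  gOracle <- mean(vapply(1:5, function(ti)
    oasOracle(epochData(ep)[, , ti]), numeric(1)))
  expect_equal(g, gOracle, tolerance = 1e-12)
  # and is averaged across subjects
  ep2 <- makeEpochs(array(rnorm(12 * 24 * 5), c(12, 24, 5)))
  g12 <- estimateCommonShrinkage(list(ep, ep2))
  expect_equal(g12, mean(c(g, estimateCommonShrinkage(ep2))),
               tolerance = 1e-12)
  expect_error(estimateCommonShrinkage(
    makeEpochs(array(0, c(1, 4, 3)))), "2 trials")
})

test_that("stratified folds keep class proportions within one trial", {
  set.seed(8)
  y <- rep(c("a", "b"), c(55, 55))[sample(110)]
  fold <- stratifiedFolds(y, 10, seed = 2)
  tab <- table(fold, y)
  expect_true(all(abs(tab[, 1] - tab[, 2]) <= 1))
  expect_equal(range(table(fold)), c(11, 11))
})

test_that("decoding finds the planted window and stays at chance elsewhere", {
  fx <- classEpochs(seed = 11)
  dr <- decodeTimecourse(fx$epochs, gamma = 0.05, nFolds = 10, seed = 1)
  acc <- accuracyTrace(dr)
  expect_gt(mean(acc[11:20]), 0.9)
  expect_lt(abs(mean(acc[-(11:20)]) - 0.5), 0.06)
  # reproducible bit-for-bit under a fixed seed
  dr2 <- decodeTimecourse(fx$epochs, gamma = 0.05, nFolds = 10, seed = 1)
  expect_identical(accuracyTrace(dr2), acc)
  expect_identical(dr2@weights, dr@weights)
  # shuffled labels: chance at every timepoint (Bonferroni-wide band)
  set.seed(12)
  tr <- fx$epochs@trials
  tr$orientation <- sample(tr$orientation)
  epSh <- new("EpochSet", data = fx$epochs@data, times = fx$epochs@times,
              lock = "stimulus", channels = fx$epochs@channels,
              trials = tr, units = "sim")
  accSh <- accuracyTrace(decodeTimecourse(epSh, gamma = 0.05, seed = 2))
  band <- qnorm(1 - 0.025 / 30) * sqrt(0.25 / 120)
  expect_true(all(abs(accSh - 0.5) <= band + 1e-9))
  # guard rails
  trU <- tr; trU$orientation[1:10] <- "vertical"
  expect_error(decodeTimecourse(new("EpochSet", data = fx$epochs@data,
    times = fx$epochs@times, lock = "stimulus",
    channels = fx$epochs@channels, trials = trU, units = "sim"),
    gamma = 0.05), "unbalanced")
})

test_that("gamma = 1 reduces the discriminant to the class-mean difference", {
  fx <- classEpochs(nTr = 80, seed = 13)
  dr <- decodeTimecourse(fx$epochs, gamma = 1, nFolds = 10, seed = 1)
  X <- epochData(fx$epochs)[, , 15]
  y <- fx$epochs@trials$orientation
  md <- colMeans(X[y == "vertical", ]) - colMeans(X[y == "horizontal", ])
  # direction parallel to the mean difference (spherical covariance)
  cs <- abs(sum(dr@weights[, 15] * md) /
              sqrt(sum(dr@weights[, 15]^2) * sum(md^2)))
  expect_gt(cs, 1 - 1e-10)
})

test_that("full-covariance LDA accuracy is affine invariant", {
  fx <- classEpochs(nTr = 80, nCh = 6, nT = 8, window = 3:6, seed = 14)
  acc1 <- accuracyTrace(decodeTimecourse(fx$epochs, gamma = 0,
                                         nFolds = 5, seed = 3))
  set.seed(15)
  A <- matrix(rnorm(36), 6, 6) + diag(6)   # invertible recombination
  d2 <- fx$epochs@data
  for (ti in 1:8) d2[, , ti] <- d2[, , ti] %*% A
  ep2 <- new("EpochSet", data = d2, times = fx$epochs@times,
             lock = "stimulus", channels = fx$epochs@channels,
             trials = fx$epochs@trials, units = "sim")
  acc2 <- accuracyTrace(decodeTimecourse(ep2, gamma = 0, nFolds = 5,
                                         seed = 3))
  expect_equal(acc1, acc2, tolerance = 1e-8)
})

test_that("activation patterns follow the forward-model identities", {
  set.seed(16)
  w <- rnorm(8)
  # identity covariance: pattern proportional to the weights
  p <- activationPatterns(w, diag(8))
  expect_equal(p, w / max(abs(w)), tolerance = 1e-12)
  # linearity in the weights
  S <- crossprod(matrix(rnorm(80), 10, 8)) / 10
  expect_equal(activationPatterns(-w, S), -activationPatterns(w, S))
  # forward-model recovery: planted generative topography
  a <- c(1, -1, 0.5, 0, 0, 0, 0, -0.5)
  y <- rnorm(2000, 0, 2)
  X <- outer(y, a) + matrix(rnorm(2000 * 8), 2000, 8)
  wLda <- solve(cov(X), colMeans(X[y > 0, ]) - colMeans(X[y <= 0, ]))
  pat <- activationPatterns(wLda, cov(X))
  expect_gt(cor(pat, a), 0.9)
  expect_error(activationPatterns(rnorm(3), diag(4)), "dimension")
  expect_error(activationPatterns(rnorm(4),
                                  matrix(rnorm(16), 4, 4)), "symmetric")
})

test_that("temporal cluster test recovers spans and controls its error rate", {
  # all subjects exactly at chance: empty result
  flat <- matrix(0.5, 8, 40)
  expect_length(temporalClusterTest(flat, nPerm = 100,
                                    seed = 1)@clusters, 0)
  # elevated accuracy in a known span
  set.seed(17)
  acc <- matrix(0.5 + rnorm(12 * 60, 0, 0.03), 12, 60)
  acc[, 25:36] <- acc[, 25:36] + 0.12
  tc <- temporalClusterTest(acc, nPerm = 1000, seed = 2,
                            times = seq(0, 295, 5))
  tab <- clusterTable(tc)
  sig <- tab[tab$significant, ]
  expect_equal(nrow(sig), 1)
  expect_lte(sig$p, 0.05)
  members <- tc@clusters[[which(tab$significant)]]$members[, 2]
  expect_gte(length(intersect(members, 25:36)) / 12, 0.8)
  # light type-I calibration (full scale in the acceptance suite)
  fwe <- vapply(1:60, function(r) {
    set.seed(300 + r)
    a0 <- matrix(0.5 + rnorm(10 * 40, 0, 0.05), 10, 40)
    any(clusterTable(temporalClusterTest(a0, nPerm = 150,
                                         seed = r))$significant)
  }, logical(1))
  expect_lte(mean(fwe), 0.13)
  expect_error(temporalClusterTest(matrix(0.5, 3, 10)), ">= 5 subjects")
})
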