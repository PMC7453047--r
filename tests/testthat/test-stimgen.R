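test_that("default display has exact region counts, spacing and determinism", {
  cfg <- stimulusConfig(seed = 7)
  d <- generateDisplay(cfg)
  el <- displayElements(d)
  expect_equal(nrow(el), 590)
  expect_equal(as.vector(table(factor(el$region,
    c("contour", "surface", "background")))), c(43, 150, 397))
  expect_true(all(el$x_px >= 0 & el$x_px <= 1000 &
                    el$y_px >= 0 & el$y_px <= 1000))
  dmin <- min(dist(cbind(el$x_px, el$y_px)))
  expect_gte(dmin, cfg@minCenterSpacingPx)
  # center displaced by the configured offset along one meridian
  off <- d@centerPx - 500
  expect_equal(sort(abs(off)), c(0, 0.69 * cfg@pxPerDeg))
  # seeded reproducibility, and a different seed gives a different layout
  expect_identical(el, displayElements(generateDisplay(cfg)))
  el2 <- displayElements(generateDisplay(stimulusConfig(seed = 8)))
  expect_false(isTRUE(all.equal(el$x_px, el2$x_px)))
})

test_that("orientations follow the cue condition rules", {
  # zero contour jitter: orientation equals the ellipse tangent exactly
  d0 <- generateDisplay(stimulusConfig(seed = 3, contourJitterSdDeg = 0))
  ct <- displayElements(d0)[displayElements(d0)$region == "contour", ]
  expect_equal(ct$orientation_deg, ct$tangent_deg, tolerance = 1e-12)
  # surface-only: surface at base -45 (+ jitter), others fixed at +45
  ds <- generateDisplay(stimulusConfig(seed = 4, condition = "surface_only",
                                       surfaceJitterSdDeg = 0))
  es <- displayElements(ds)
  expect_true(all(es$orientation_deg[es$region == "surface"] == -45))
  expect_true(all(es$orientation_deg[es$region != "surface"] == 45))
  # combined: surface around the base orientation with the requested spread
  dc <- generateDisplay(stimulusConfig(seed = 5, condition = "combined",
                                       surfaceJitterSdDeg = 10))
  ec <- displayElements(dc)
  dev <- ec$orientation_deg[ec$region == "surface"] + 45
  expect_lt(abs(mean(dev)), 5)
  expect_gt(sd(dev), 5)
  # contour-only: surface and background uniform over [0, 180)
  d1 <- generateDisplay(stimulusConfig(seed = 6, condition = "contour_only"))
  e1 <- displayElements(d1)
  bg <- e1$orientation_deg[e1$region != "contour"]
  expect_true(all(bg >= 0 & bg < 180))
  expect_gt(suppressWarnings(stats::ks.test(bg / 180, "punif")$p.value),
            0.01)
})

test_that("pooled contour jitter deviations recover the generating SD", {
  # small display variant keeps packing cheap; the contour count is the
  # design's 43 so 200 displays pool 8600 deviation draws
  dev <- unlist(lapply(1:200, function(s) {
    cfg <- stimulusConfig(seed = s, contourJitterSdDeg = 65,
                          nSurface = 40, nBackground = 120,
                          minCenterSpacingPx = 20)
    el <- displayElements(generateDisplay(cfg))
    ct <- el$region == "contour"
    el$orientation_deg[ct] - el$tangent_deg[ct]
  }))
  expect_equal(length(dev), 200 * 43)
  expect_lt(abs(sd(dev) - 65), 3)
})

test_that("density check matches a direct Welch t-test oracle", {
  d <- generateDisplay(stimulusConfig(seed = 11))
  el <- displayElements(d)
  for (within in c(FALSE, TRUE)) {
    rep <- densityCheck(d, withinRegion = within)
    nn4 <- bruteNN4(el$x_px, el$y_px,
                    group = if (within) el$region else NULL)
    sp <- split(nn4, factor(el$region,
                            c("contour", "surface", "background")))
    oracle <- c(
      t.test(sp$contour, sp$surface, var.equal = FALSE)$p.value,
      t.test(sp$contour, sp$background, var.equal = FALSE)$p.value,
      t.test(sp$surface, sp$background, var.equal = FALSE)$p.value)
    expect_equal(unname(rep$pairwise_p), oracle, tolerance = 1e-12)
    expect_identical(rep$accepted, all(oracle > 0.1))
  }
})

test_that("density check flags compressed regions and passes exchangeable ones", {
  d <- generateDisplay(stimulusConfig(seed = 2))
  el <- displayElements(d)
  # compress surface elements halfway toward the ellipse center
  sf <- el$region == "surface"
  el2 <- el
  el2$x_px[sf] <- d@centerPx[1] + (el$x_px[sf] - d@centerPx[1]) / 2
  el2$y_px[sf] <- d@centerPx[2] + (el$y_px[sf] - d@centerPx[2]) / 2
  d2 <- new("StimulusDisplay", config = d@config, elements = el2,
            centerPx = d@centerPx, density = list())
  rep <- densityCheck(d2)
  expect_lt(rep$pairwise_p[["surface_vs_background"]], 0.1)
  expect_false(rep$accepted)
  # three identical, well-separated grids: constant equal distances
  g <- expand.grid(x = seq(0, 120, 30), y = seq(0, 120, 30))
  el3 <- data.frame(
    x_px = c(g$x, g$x + 300, g$x + 600), y_px = rep(g$y, 3) + 100,
    orientation_deg = 0,
    region = rep(c("contour", "surface", "background"), each = nrow(g)),
    tangent_deg = NA_real_)
  cfg3 <- stimulusConfig(nContour = nrow(g), nSurface = nrow(g),
                         nBackground = nrow(g))
  d3 <- new("StimulusDisplay", config = cfg3, elements = el3,
            centerPx = c(500, 500), density = list())
  rep3 <- densityCheck(d3)
  expect_true(all(rep3$pairwise_p == 1))
  expect_true(rep3$accepted)
})

test_that("label-permuted null displays reject near the filter's nominal level", {
  # all regions share one placement process, labels are exchangeable, so
  # the only signal is sampling noise; with three correlated alpha-0.1
  # tests the family-wise rejection rate must sit between alpha and
  # 1 - (1 - alpha)^3
  rejected <- vapply(1:200, function(s) {
    cfg <- stimulusConfig(seed = s, nContour = 50, nSurface = 50,
                          nBackground = 50, minCenterSpacingPx = 20)
    d <- generateDisplay(cfg)
    el <- displayElements(d)
    set.seed(1000 + s)
    el$region <- sample(el$region)
    el$tangent_deg <- NA_real_
    d2 <- new("StimulusDisplay", config = cfg, elements = el,
              centerPx = d@centerPx, density = list())
    !densityCheck(d2)$accepted
  }, logical(1))
  rate <- mean(rejected)
  expect_gt(rate, 0.05)
  expect_lt(rate, 0.40)
})

test_that("gabor rendering: carrier contrast, rotation, zero contrast, masks", {
  # Michelson contrast of the carrier under a broad envelope
  g <- gaborPatch(101, 0, 0.1, 50, phase = pi / 2, contrast = 0.5)
  expect_equal((max(g) - min(g)) / (max(g) + min(g)), 0.5,
               tolerance = 0.02)
  # rotating the orientation by 90 deg rotates the (peak-aligned) patch
  p1 <- gaborPatch(31, 20, 0.07, 6, phase = pi / 2, contrast = 0.8)
  p2 <- gaborPatch(31, 110, 0.07, 6, phase = pi / 2, contrast = 0.8)
  rot90ccw <- function(m) t(m[, rev(seq_len(ncol(m)))])
  expect_equal(p2, rot90ccw(p1), tolerance = 1e-10)
  # zero contrast renders flat mid-grey
  expect_true(all(gaborPatch(31, 33, 0.07, 6, 1.1, 0) == 0.5))
  # full display render stays in [0, 1] on a mid-grey background
  cfg <- stimulusConfig(seed = 1, displayPx = 200, pxPerDeg = 12.5,
                        ellipseMajorDeg = 10.2, nContour = 12,
                        nSurface = 15, nBackground = 40,
                        minCenterSpacingPx = 12)
  img <- renderDisplay(generateDisplay(cfg))
  expect_equal(dim(img), c(200, 200))
  expect_true(all(img >= 0 & img <= 1))
  expect_equal(img[1, 1], 0.5)
  # noise masks: uniform values, exact size, seeded
  m <- makeNoiseMask(64, seed = 9)
  expect_equal(dim(m), c(64, 64))
  expect_true(all(m >= 0 & m <= 1))
  expect_identical(m, makeNoiseMask(64, seed = 9))
  expect_false(identical(m, makeNoiseMask(64, seed = 10)))
})

test_that("display table round trip and error paths", {
  d <- generateDisplay(stimulusConfig(seed = 1, displayPx = 300,
                                      pxPerDeg = 300 / 16, nContour = 12,
                                      nSurface = 20, nBackground = 60,
                                      minCenterSpacingPx = 10))
  path <- tempfile(fileext = ".tsv")
  writeDisplayTable(d, path)
  rt <- readDisplayTable(path)
  expect_equal(rt$x_px, displayElements(d)$x_px, tolerance = 1e-6)
  expect_equal(rt$region, displayElements(d)$region)
  # impossible packing densities fail with an informative error
  expect_error(generateDisplay(stimulusConfig(displayPx = 100,
    pxPerDeg = 100 / 16, nContour = 12, nSurface = 150, nBackground = 397,
    minCenterSpacingPx = 30), maxTriesPerElement = 20),
    "packing failure")
  # invalid configurations are rejected up front
  expect_error(stimulusConfig(axisRatio = 0.9), "axisRatio")
  expect_error(stimulusConfig(gaborContrast = 1.4), "Contrast")
  expect_error(stimulusConfig(contourJitterSdDeg = -1), "jitter")
  # density check needs at least 5 elements per region
  expect_error(densityCheck(generateDisplay(stimulusConfig(
    seed = 1, displayPx = 300, pxPerDeg = 300 / 16, nContour = 12,
    nSurface = 4, nBackground = 60, minCenterSpacingPx = 10))),
    ">= 5 elements")
})
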