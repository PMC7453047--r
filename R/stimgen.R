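## Gaborized ellipse display generation: element placement with a minimum
## center-spacing constraint, cue (orientation jitter) assignment, local
## density control, and rendering.

#' Construct a stimulus display configuration
#'
#' Returns a [StimulusConfig-class] with the default display design: a
#' 1000 x 1000 px field holding 590 non-overlapping Gabor elements split
#' into 43 contour, 150 surface and 397 background elements, an embedded
#' ellipse with major axis 10.2 deg and axis ratio 1.2, carrier spatial
#' frequency 3 cycles per 0.7 deg at 50 percent Michelson contrast under a
#' 3.8-arcmin Gaussian envelope, and a random center displacement of
#' 0.69 deg along one meridian.
#'
#' Cue reliability is controlled by `contourJitterSdDeg` and
#' `surfaceJitterSdDeg`: the orientation of each active cue element is its
#' noiseless value (ellipse tangent for contour, `surfaceBaseOrientationDeg`
#' for surface) plus an i.i.d. Gaussian deviation with that SD.
#'
#' @param displayPx pixels per side of the square display.
#' @param pxPerDeg pixels per degree of visual angle.
#' @param nContour,nSurface,nBackground element counts per region.
#' @param ellipseMajorDeg,axisRatio ellipse major axis (deg) and major/minor
#'   ratio.
#' @param ellipseOrientation `"vertical"` or `"horizontal"`.
#' @param condition `"contour_only"`, `"surface_only"` or `"combined"`.
#' @param contourJitterSdDeg,surfaceJitterSdDeg orientation jitter SDs, deg.
#' @param surfaceBaseOrientationDeg base orientation of surface elements
#'   (deg from vertical, positive clockwise).
#' @param nonsurfaceBaseOrientationDeg orientation given to contour and
#'   background elements in the surface-only condition.
#' @param centerOffsetDeg magnitude of the seeded center displacement, deg.
#' @param gaborSfCycPerDeg,gaborContrast,gaborEnvelopeSdArcmin Gabor carrier
#'   and envelope parameters.
#' @param minCenterSpacingPx minimum pairwise center distance, px.
#' @param seed integer RNG seed.
#' @return a validated [StimulusConfig-class].
#' @examples
#' cfg <- stimulusConfig(condition = "combined", contourJitterSdDeg = 13.8)
#' @export
stimulusConfig <- function(displayPx = 1000, pxPerDeg = 62.5,
                           nContour = 43, nSurface = 150, nBackground = 397,
                           ellipseMajorDeg = 10.2, axisRatio = 1.2,
                           ellipseOrientation = "vertical",
                           condition = "combined",
                           contourJitterSdDeg = 0, surfaceJitterSdDeg = 0,
                           surfaceBaseOrientationDeg = -45,
                           nonsurfaceBaseOrientationDeg = 45,
                           centerOffsetDeg = 0.69,
                           gaborSfCycPerDeg = 3 / 0.7, gaborContrast = 0.5,
                           gaborEnvelopeSdArcmin = 3.8,
                           minCenterSpacingPx = 30, seed = 1L) {
  new("StimulusConfig", displayPx = displayPx, pxPerDeg = pxPerDeg,
      nContour = nContour, nSurface = nSurface, nBackground = nBackground,
      ellipseMajorDeg = ellipseMajorDeg, axisRatio = axisRatio,
      ellipseOrientation = ellipseOrientation, condition = condition,
      contourJitterSdDeg = contourJitterSdDeg,
      surfaceJitterSdDeg = surfaceJitterSdDeg,
      surfaceBaseOrientationDeg = surfaceBaseOrientationDeg,
      nonsurfaceBaseOrientationDeg = nonsurfaceBaseOrientationDeg,
      centerOffsetDeg = centerOffsetDeg,
      gaborSfCycPerDeg = gaborSfCycPerDeg, gaborContrast = gaborContrast,
      gaborEnvelopeSdArcmin = gaborEnvelopeSdArcmin,
      minCenterSpacingPx = minCenterSpacingPx, seed = seed)
}

## Ellipse outline points and tangents at parameter angles `tt`.
## Orientation "vertical" puts the major axis along y.
ellipseXY <- function(tt, center, aPx, bPx, orientation) {
  if (orientation == "vertical") {
    list(x = center[1] + bPx * cos(tt), y = center[2] + aPx * sin(tt),
         dx = -bPx * sin(tt), dy = aPx * cos(tt))
  } else {
    list(x = center[1] + aPx * cos(tt), y = center[2] + bPx * sin(tt),
         dx = -aPx * sin(tt), dy = bPx * cos(tt))
  }
}

## Normalized ellipse radius (1 on the outline) of points (x, y).
ellipseRadius <- function(x, y, center, aPx, bPx, orientation) {
  if (orientation == "vertical")
    sqrt(((x - center[1]) / bPx)^2 + ((y - center[2]) / aPx)^2)
  else
    sqrt(((x - center[1]) / aPx)^2 + ((y - center[2]) / bPx)^2)
}

## Grid-hash occupancy structure for minimum-spacing rejection sampling.
newSpacingGrid <- function(displayPx, spacing) {
  cell <- max(spacing, 1)
  n <- ceiling(displayPx / cell) + 2L
  list(cell = cell, n = n, pts = vector("list", n * n),
       px = numeric(0), py = numeric(0))
}

gridIndex <- function(g, x, y) {
  ix <- pmin(pmax(floor(x / g$cell), 0), g$n - 3L) + 2L
  iy <- pmin(pmax(floor(y / g$cell), 0), g$n - 3L) + 2L
  (ix - 1L) * g$n + iy
}

gridOk <- function(g, x, y, spacing) {
  ix <- pmin(pmax(floor(x / g$cell), 0), g$n - 3L) + 2L
  iy <- pmin(pmax(floor(y / g$cell), 0), g$n - 3L) + 2L
  for (dx in -1:1) for (dy in -1:1) {
    ids <- g$pts[[(ix + dx - 1L) * g$n + (iy + dy)]]
    if (length(ids) &&
        any((g$px[ids] - x)^2 + (g$py[ids] - y)^2 < spacing^2))
      return(FALSE)
  }
  TRUE
}

gridAdd <- function(g, x, y) {
  g$px <- c(g$px, x); g$py <- c(g$py, y)
  id <- length(g$px)
  k <- gridIndex(g, x, y)
  g$pts[[k]] <- c(g$pts[[k]], id)
  g
}

#' Generate one Gaborized ellipse display
#'
#' Places the configured number of contour, surface and background elements
#' in the display with dart-throwing under the minimum center-spacing
#' constraint, then assigns orientations according to the cue condition:
#' contour elements take the local ellipse-tangent orientation (plus
#' Gaussian jitter) when the contour cue is active, surface elements the
#' iso-orientation base (plus jitter) when the surface cue is active, and
#' inactive regions are uniformly random -- except in the surface-only
#' condition, where contour and background elements are fixed at
#' `nonsurfaceBaseOrientationDeg`.  Contour elements sit at equal
#' arc-length spacing along the outline (random rotational phase); the
#' ellipse center is displaced by `centerOffsetDeg` along one of the four
#' half-meridians, chosen at random.  Fully deterministic for a fixed
#' `config@seed`.
#'
#' Stored `orientation_deg` values are left unwrapped (tangent + deviation)
#' so that jitter draws can be recovered exactly; orientations are
#' equivalent modulo 180 deg.
#'
#' @param config a [StimulusConfig-class].
#' @param maxTriesPerElement candidate draws allowed per element before the
#'   placement is declared infeasible.
#' @return a [StimulusDisplay-class].
#' @examples
#' disp <- generateDisplay(stimulusConfig(seed = 7))
#' table(displayElements(disp)$region)
#' @export
generateDisplay <- function(config, maxTriesPerElement = 400) {
  validObject(config)
  withSeed(config@seed, {
    px <- config@displayPx
    spacing <- config@minCenterSpacingPx
    aPx <- config@ellipseMajorDeg / 2 * config@pxPerDeg
    bPx <- aPx / config@axisRatio
    offPx <- config@centerOffsetDeg * config@pxPerDeg
    meridian <- sample(4L, 1L)
    center <- c(px / 2, px / 2) +
      switch(meridian, c(offPx, 0), c(-offPx, 0), c(0, offPx), c(0, -offPx))

    ## contour: equal arc-length positions with a random rotational phase
    fine <- seq(0, 2 * pi, length.out = 4096L)
    pts <- ellipseXY(fine, center, aPx, bPx, config@ellipseOrientation)
    seg <- sqrt(diff(pts$x)^2 + diff(pts$y)^2)
    arc <- c(0, cumsum(seg))
    total <- arc[length(arc)]
    target <- (runif(1) * total + (seq_len(config@nContour) - 1) *
                 total / config@nContour) %% total
    tc <- approx(arc, fine, xout = target, rule = 2)$y
    cpt <- ellipseXY(tc, center, aPx, bPx, config@ellipseOrientation)
    tangent <- (atan2(cpt$dx, cpt$dy) * 180 / pi) %% 180

    grid <- newSpacingGrid(px, spacing)
    for (i in seq_len(config@nContour)) {
      stopIf(!gridOk(grid, cpt$x[i], cpt$y[i], spacing),
             "packing failure in contour region: outline points closer than ",
             "minCenterSpacingPx; reduce nContour or spacing")
      stopIf(cpt$x[i] < 0 || cpt$x[i] > px || cpt$y[i] < 0 || cpt$y[i] > px,
             "ellipse outline leaves the display; reduce ellipseMajorDeg or ",
             "centerOffsetDeg")
      grid <- gridAdd(grid, cpt$x[i], cpt$y[i])
    }

    ## surface and background elements come from one homogeneous
    ## dart-throwing process over the display (region = inside/outside the
    ## outline), so local density carries no shape cue.  The two region
    ## quotas are interleaved in a random order so that late, hole-filling
    ## placements (which sit closer to their neighbors) are shared
    ## proportionally between regions rather than piling up in whichever
    ## region fills last.
    nS <- config@nSurface; nB <- config@nBackground
    sx <- numeric(nS); sy <- numeric(nS)
    bx <- numeric(nB); by <- numeric(nB)
    wantInside <- sample(rep(c(TRUE, FALSE), c(nS, nB)))
    placedS <- 0L; placedB <- 0L; tries <- 0L
    budget <- maxTriesPerElement * max(nS + nB, 1)
    for (k in seq_along(wantInside)) {
      repeat {
        tries <- tries + 1L
        stopIf(tries > budget, "packing failure in ",
               if (wantInside[k]) "surface" else "background",
               " region after ", budget, " candidate draws; reduce counts ",
               "or minCenterSpacingPx")
        x <- runif(1, 0, px); y <- runif(1, 0, px)
        r <- ellipseRadius(x, y, center, aPx, bPx,
                           config@ellipseOrientation)
        if ((r < 1) != wantInside[k]) next
        if (!gridOk(grid, x, y, spacing)) next
        break
      }
      if (wantInside[k]) {
        placedS <- placedS + 1L
        sx[placedS] <- x; sy[placedS] <- y
      } else {
        placedB <- placedB + 1L
        bx[placedB] <- x; by[placedB] <- y
      }
      grid <- gridAdd(grid, x, y)
    }
    srf <- list(x = sx, y = sy)
    bkg <- list(x = bx, y = by)

    contourActive <- config@condition %in% c("contour_only", "combined")
    surfaceActive <- config@condition %in% c("surface_only", "combined")

    oriContour <- if (contourActive) {
      tangent + rnorm(config@nContour, 0, config@contourJitterSdDeg)
    } else if (config@condition == "surface_only") {
      rep(config@nonsurfaceBaseOrientationDeg, config@nContour)
    } else runif(config@nContour, 0, 180)

    oriSurface <- if (surfaceActive) {
      config@surfaceBaseOrientationDeg +
        rnorm(config@nSurface, 0, config@surfaceJitterSdDeg)
    } else runif(config@nSurface, 0, 180)

    oriBackground <- if (config@condition == "surface_only") {
      rep(config@nonsurfaceBaseOrientationDeg, config@nBackground)
    } else runif(config@nBackground, 0, 180)

    elements <- data.frame(
      x_px = c(cpt$x, srf$x, bkg$x),
      y_px = c(cpt$y, srf$y, bkg$y),
      orientation_deg = c(oriContour, oriSurface, oriBackground),
      region = rep(c("contour", "surface", "background"),
                   c(config@nContour, config@nSurface, config@nBackground)),
      tangent_deg = c(tangent, rep(NA_real_,
                                   config@nSurface + config@nBackground)))
    new("StimulusDisplay", config = config, elements = elements,
        centerPx = center, density = list())
  })
}

#' Local density check across display regions
#'
#' For every element, computes the mean Euclidean distance to its four
#' nearest neighbors, then compares these per-element means between each
#' pair of regions with Welch's unequal-variance two-sample t-test.  A
#' display is accepted when no pair differs at the given alpha, i.e. when
#' local density carries no cue to the embedded shape.
#'
#' @param display a [StimulusDisplay-class].
#' @param alpha rejection level per pairwise test (default 0.1).
#' @param withinRegion if `TRUE`, restrict the nearest-neighbor search to
#'   elements of the same region; by default neighbors are searched over all
#'   elements.
#' @return a list with `mean_nn4_by_region` (named numeric), `pairwise_p`
#'   (named numeric, three region pairs), `alpha` and `accepted`.
#' @examples
#' disp <- generateDisplay(stimulusConfig(seed = 2))
#' densityCheck(disp)$accepted
#' @export
densityCheck <- function(display, alpha = 0.1, withinRegion = FALSE) {
  el <- displayElements(display)
  regions <- c("contour", "surface", "background")
  counts <- table(factor(el$region, levels = regions))
  stopIf(any(counts < 5), "density check needs >= 5 elements per region; ",
         "got ", paste(counts, collapse = "/"))
  nn4 <- meanNN4(el$x_px, el$y_px,
                 group = if (withinRegion) el$region else NULL)
  byRegion <- split(nn4, factor(el$region, levels = regions))
  pairs <- utils::combn(regions, 2)
  pw <- apply(pairs, 2, function(pr) {
    a <- byRegion[[pr[1]]]; b <- byRegion[[pr[2]]]
    if (sd(a) == 0 && sd(b) == 0 && isTRUE(all.equal(mean(a), mean(b))))
      return(1)  # identical constant samples: no evidence of difference
    t.test(a, b, var.equal = FALSE)$p.value
  })
  names(pw) <- apply(pairs, 2, paste, collapse = "_vs_")
  list(mean_nn4_by_region = vapply(byRegion, mean, numeric(1)),
       pairwise_p = pw, alpha = alpha, accepted = all(pw > alpha))
}

## Mean distance to the 4 nearest neighbors for each point; `group`
## optionally restricts the search within groups.
meanNN4 <- function(x, y, group = NULL) {
  n <- length(x)
  d <- as.matrix(dist(cbind(x, y)))
  diag(d) <- Inf
  if (!is.null(group)) d[outer(group, group, "!=")] <- Inf
  apply(d, 1, function(r) mean(sort(r, partial = 4)[1:4]))
}

#' Render a single Gabor patch
#'
#' The product of an oriented sine-wave luminance grating and a circular
#' Gaussian envelope, on a mid-grey (0.5) background, clipped to \[0, 1\].
#' Orientation is in degrees from vertical, positive clockwise; a phase of
#' `pi/2` peak-aligns the carrier at the patch center.
#'
#' @param sizePx side of the (square, odd-sized) patch, px.
#' @param orientationDeg carrier orientation, deg from vertical.
#' @param sfCycPerPx carrier spatial frequency, cycles per pixel.
#' @param sigmaPx envelope SD, px.
#' @param phase carrier phase, radians.
#' @param contrast Michelson contrast of the carrier, \[0, 1\].
#' @return numeric matrix `sizePx` x `sizePx` with values in \[0, 1\].
#' @export
gaborPatch <- function(sizePx, orientationDeg, sfCycPerPx, sigmaPx,
                       phase = pi / 2, contrast = 0.5) {
  stopIf(sizePx %% 2 == 0, "sizePx must be odd so the patch has a center pixel")
  h <- (sizePx - 1) / 2
  xs <- seq(-h, h)
  th <- orientationDeg * pi / 180
  proj <- outer(xs, xs, function(y, x) x * cos(th) - y * sin(th))
  r2 <- outer(xs^2, xs^2, "+")
  0.5 + 0.5 * contrast * sin(2 * pi * sfCycPerPx * proj + phase) *
    exp(-r2 / (2 * sigmaPx^2))
}

#' Render a display to a grayscale image matrix
#'
#' Draws every Gabor element of the display onto a mid-grey background.
#' Carrier phases are uniform-random per element (seeded) unless
#' `phase = "aligned"`, which peak-aligns every carrier at the element
#' center.  Values are clipped to \[0, 1\]; the matrix is row-major
#' top-down, suitable for [png::writePNG()].
#'
#' @param display a [StimulusDisplay-class].
#' @param phase `"random"` or `"aligned"`.
#' @param seed RNG seed for the per-element phases (defaults to the display
#'   config seed).
#' @return numeric matrix `displayPx` x `displayPx` in \[0, 1\].
#' @export
renderDisplay <- function(display, phase = c("random", "aligned"),
                          seed = NULL) {
  phase <- match.arg(phase)
  cfg <- display@config
  el <- displayElements(display)
  seed <- seed %||% cfg@seed
  img <- matrix(0.5, cfg@displayPx, cfg@displayPx)
  sigmaPx <- cfg@gaborEnvelopeSdArcmin / 60 * cfg@pxPerDeg
  sfPx <- cfg@gaborSfCycPerDeg / cfg@pxPerDeg
  half <- max(5L, ceiling(4 * sigmaPx))
  n <- nrow(el)
  phases <- withSeed(seed, if (phase == "random")
    runif(n, 0, 2 * pi) else rep(pi / 2, n))
  for (i in seq_len(n)) {
    cx <- round(el$x_px[i]); cy <- round(el$y_px[i])
    patch <- gaborPatch(2L * half + 1L, el$orientation_deg[i], sfPx,
                        sigmaPx, phases[i], cfg@gaborContrast) - 0.5
    rows <- (cy - half):(cy + half)   # image row = y (top-down)
    cols <- (cx - half):(cx + half)
    keepR <- rows >= 1 & rows <= cfg@displayPx
    keepC <- cols >= 1 & cols <= cfg@displayPx
    img[rows[keepR], cols[keepC]] <-
      img[rows[keepR], cols[keepC]] + patch[keepR, keepC]
  }
  pmin(pmax(img, 0), 1)
}

#' Uniform pixel-noise mask
#'
#' Square mask with each pixel intensity drawn independently from the
#' uniform distribution on \[0, 1\]; used to backward-mask stimulus
#' displays.
#'
#' @param sizePx pixels per side (default 1000).
#' @param seed RNG seed.
#' @return numeric matrix `sizePx` x `sizePx`.
#' @export
makeNoiseMask <- function(sizePx = 1000, seed = 1L) {
  withSeed(seed, matrix(runif(sizePx * sizePx), sizePx, sizePx))
}

#' Equidistant jitter levels
#'
#' The six-level constant-stimuli ladder of orientation jitter SDs used in
#' the behavioral session: `n` equidistant values from `minDeg` to
#' `maxDeg`, defaults reproducing 1, 13.8, 26.6, 39.4, 52.2, 65 degrees.
#'
#' @param minDeg,maxDeg endpoints, degrees.
#' @param n number of levels.
#' @return numeric vector of jitter SDs, degrees.
#' @examples
#' jitterLevels()
#' @export
jitterLevels <- function(minDeg = 1, maxDeg = 65, n = 6) {
  stopIf(n < 2, "need at least 2 levels")
  seq(minDeg, maxDeg, length.out = n)
}

#' Write / read a display element table
#'
#' Tab-separated text, one row per element with columns `x_px`, `y_px`,
#' `orientation_deg`, `region`, `tangent_deg`.
#'
#' @param display a [StimulusDisplay-class].
#' @param path file path.
#' @return `readDisplayTable` returns the element `data.frame`.
#' @export
writeDisplayTable <- function(display, path) {
  write.table(displayElements(display), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname writeDisplayTable
#' @export
readDisplayTable <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Write a rendered display (or noise mask) as an 8-bit grayscale PNG
#'
#' @param img numeric matrix in \[0, 1\] from [renderDisplay()] or
#'   [makeNoiseMask()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeDisplayImage <- function(img, path) {
  png::writePNG(img, path)
  invisible(path)
}
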