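## Peak-aligned component analysis: per-subject peak electrode/latency
## detection inside component search windows, and multilevel (random
## intercept) regression of peak amplitude on log jitter and condition with
## backward likelihood-ratio model simplification.

#' Default component search windows
#'
#' Search windows for the three evoked components reliably identifiable in
#' this paradigm (near 90, 307 and 402 ms).  These are configuration
#' defaults, not claims about any particular dataset.
#'
#' @return named list of `c(lo, hi)` windows in ms.
#' @export
componentWindows <- function() {
  list(C100 = c(60, 140), C300 = c(250, 350), C400 = c(350, 480))
}

#' Detect individual component peaks
#'
#' Per subject: averages all trials (across conditions and jitter levels),
#' selects within each search window the electrode with the highest
#' activity (largest absolute mean amplitude by default, or signed for a
#' fixed-polarity component), takes the latency of the extremum at that
#' electrode, and reads out the per-condition x per-level mean amplitude at
#' that electrode and latency.  Peaks lying on a window boundary are
#' flagged (`boundary = TRUE`) -- such subject/component entries should be
#' excluded from the regression rather than trusted.
#'
#' @param epochs an [EpochSet-class] (typically average-referenced, not
#'   rectified); trials need `subject`, `condition`, `jitter_deg`.
#' @param windows named list of `c(lo, hi)` windows, ms (default
#'   [componentWindows()]).
#' @param polarity `"abs"`, `"positive"` or `"negative"`.
#' @return `data.frame` (one row per subject x component x condition x
#'   level): `subject`, `component`, `electrode`, `latency_ms`,
#'   `boundary`, `condition`, `jitter_deg`, `amplitude`.
#' @export
findComponentPeaks <- function(epochs, windows = componentWindows(),
                               polarity = c("abs", "positive", "negative")) {
  stopifnot(is(epochs, "EpochSet"))
  polarity <- match.arg(polarity)
  times <- epochs@times
  for (w in windows)
    stopIf(w[1] < min(times) || w[2] > max(times),
           "component window outside the epoch")
  tr <- epochs@trials
  stopIf(is.null(tr$subject) || is.null(tr$condition) ||
           is.null(tr$jitter_deg),
         "trial table needs subject, condition, jitter_deg")
  score <- switch(polarity, abs = abs, positive = identity,
                  negative = function(x) -x)
  out <- list()
  for (s in unique(tr$subject)) {
    rows <- which(tr$subject == s)
    avg <- apply(epochs@data[rows, , , drop = FALSE], c(2, 3), mean)
    for (nm in names(windows)) {
      w <- windows[[nm]]
      tin <- which(times >= w[1] & times <= w[2])
      sub <- score(avg[, tin, drop = FALSE])
      elec <- which.max(apply(sub, 1, max))
      lat <- tin[which.max(sub[elec, ])]
      boundary <- lat == tin[1] || lat == tin[length(tin)] ||
        max(sub) - min(sub) < .Machine$double.eps^0.5
      for (cond in unique(tr$condition[rows])) {
        for (j in sort(unique(tr$jitter_deg[rows]))) {
          cells <- rows[tr$condition[rows] == cond &
                          tr$jitter_deg[rows] == j]
          out[[length(out) + 1L]] <- data.frame(
            subject = s, component = nm,
            electrode = epochs@channels[elec],
            latency_ms = times[lat], boundary = boundary,
            condition = cond, jitter_deg = j,
            amplitude = mean(epochs@data[cells, elec, lat]))
        }
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Multilevel regression of peak amplitude with LRT simplification
#'
#' Fits, by maximum likelihood, the random-intercept-per-subject model
#' `amplitude ~ log(jitter) * condition + (1 | subject)` and simplifies it
#' backward: drop the interaction, then condition, then jitter, each step
#' tested with a likelihood-ratio test and stopping as soon as a drop
#' significantly worsens the fit at `alpha`.  Boundary-flagged peaks are
#' excluded first.
#'
#' @param peaks a peak table from [findComponentPeaks()], restricted to one
#'   component (or pass `component` to select one).
#' @param component optional component label to filter on.
#' @param alpha LRT significance level for keeping a term.
#' @return list with `selected` (model label: `"full"`,
#'   `"jitter+condition"`, `"jitter"`, `"intercept"`), `model` (the
#'   selected `lmerMod`), `fixef` (its fixed effects), `lrt`
#'   (`data.frame` of the tested drops: term, chisq, df, p), `nDropped`
#'   (boundary exclusions).
#' @export
fitComponentModel <- function(peaks, component = NULL, alpha = 0.05) {
  if (!is.null(component)) peaks <- peaks[peaks$component == component, ]
  stopIf(nrow(peaks) == 0, "empty peak table")
  stopIf(length(unique(peaks$component)) > 1,
         "peak table spans several components; pass `component`")
  nDropped <- sum(peaks$boundary)
  peaks <- peaks[!peaks$boundary, ]
  nSubj <- length(unique(peaks$subject))
  nCond <- length(unique(peaks$condition))
  nLev <- length(unique(peaks$jitter_deg))
  stopIf(nSubj < 5 || nCond < 2 || nLev < 3,
         "need >= 5 subjects, >= 2 conditions and >= 3 levels; got ",
         nSubj, "/", nCond, "/", nLev)
  full_cells <- nSubj * nCond * nLev
  stopIf(nrow(peaks) < 0.8 * full_cells,
         "more than 20% of subject x condition x level cells are missing")
  peaks$logj <- log(peaks$jitter_deg)
  peaks$condition <- factor(peaks$condition)

  forms <- list(
    full = amplitude ~ logj * condition + (1 | subject),
    `jitter+condition` = amplitude ~ logj + condition + (1 | subject),
    jitter = amplitude ~ logj + (1 | subject),
    intercept = amplitude ~ 1 + (1 | subject))
  fits <- lapply(forms, function(f)
    lme4::lmer(f, data = peaks, REML = FALSE))
  terms <- c("interaction", "condition", "jitter")

  lrt <- data.frame(term = character(), chisq = numeric(), df = numeric(),
                    p = numeric())
  selected <- "intercept"
  for (i in 1:3) {
    a <- stats::anova(fits[[i + 1]], fits[[i]])
    chisq <- a$Chisq[2]; df <- a$Df[2]; p <- a$`Pr(>Chisq)`[2]
    lrt <- rbind(lrt, data.frame(term = terms[i], chisq = chisq, df = df,
                                 p = p))
    if (p < alpha) { selected <- names(forms)[i]; break }
  }
  list(selected = selected, model = fits[[selected]],
       fixef = lme4::fixef(fits[[selected]]), lrt = lrt,
       nDropped = nDropped)
}

#' Simulate a peak-amplitude table from the multilevel generative model
#'
#' Draws per-subject random intercepts and residual noise around fixed
#' effects on log jitter, condition and their interaction; used for power
#' and specificity checks of the LRT simplification chain.
#'
#' @param nSubjects,conditions,jitter design.
#' @param intercept,slope,conditionEffect,interaction fixed effects (the
#'   second condition gets `conditionEffect` added to its intercept and
#'   `interaction` added to its slope).
#' @param sdSubject,sdResidual random-intercept and residual SDs.
#' @param seed RNG seed.
#' @return a peak table suitable for [fitComponentModel()] (component
#'   label `"sim"`, no boundary flags).
#' @export
simulatePeakTable <- function(nSubjects = 16,
                              conditions = c("contour_fixed",
                                             "surface_fixed"),
                              jitter = veplink::jitterLevels(),
                              intercept = 0, slope = 0,
                              conditionEffect = 0, interaction = 0,
                              sdSubject = 1, sdResidual = 1.5,
                              seed = 1L) {
  withSeed(seed, {
    g <- expand.grid(subject = sprintf("S%02d", seq_len(nSubjects)),
                     condition = conditions, jitter_deg = jitter,
                     stringsAsFactors = FALSE)
    u <- rnorm(nSubjects, 0, sdSubject)
    names(u) <- sprintf("S%02d", seq_len(nSubjects))
    second <- as.numeric(g$condition == conditions[2])
    g$amplitude <- intercept + u[g$subject] + slope * log(g$jitter_deg) +
      conditionEffect * second +
      interaction * second * log(g$jitter_deg) +
      rnorm(nrow(g), 0, sdResidual)
    g$component <- "sim"; g$electrode <- "E001"
    g$latency_ms <- 402; g$boundary <- FALSE
    g
  })
}
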