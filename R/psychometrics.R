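## Four-parameter probit psychometrics, d-prime transformation and the
## log-log d-prime/jitter linking regression.

#' Evaluate the four-parameter probit psychometric function
#'
#' \eqn{P(j) = g + (1 - g - l)\,\Phi((\mu - j)/s)}: proportion correct as a
#' decreasing function of orientation jitter SD.
#'
#' @param fit a [PsychometricFit-class], or a numeric vector
#'   `c(mu, scale, guess, lapse)`.
#' @param jitter jitter SD values, degrees.
#' @return predicted proportions correct.
#' @export
evaluateProbit <- function(fit, jitter) {
  p <- probitPars(fit)
  unname(p[["guess"]] + (1 - p[["guess"]] - p[["lapse"]]) *
           pnorm((p[["mu"]] - jitter) / p[["scale"]]))
}

probitPars <- function(fit) {
  if (is(fit, "PsychometricFit"))
    c(mu = fit@mu, scale = fit@scale, guess = fit@guess, lapse = fit@lapse)
  else setNames(as.numeric(fit), c("mu", "scale", "guess", "lapse"))
}

probitNegLL <- function(par, jitter, k, n) {
  p <- pmin(pmax(par[3] + (1 - par[3] - par[4]) *
                   pnorm((par[1] - jitter) / par[2]), 1e-10), 1 - 1e-10)
  -sum(k * log(p) + (n - k) * log1p(-p))
}

#' Fit the four-parameter probit psychometric function
#'
#' Maximum-likelihood (binomial) fit of proportion correct against jitter
#' SD, with guess and lapse free within \[0, 0.5\].  Uses bounded
#' quasi-Newton (`optim`, L-BFGS-B) from multiple seeded starting points
#' and keeps the best likelihood.  The `converged` flag is `FALSE` when the
#' data carry no level information (performance flat across levels), in
#' which case parameter values should not be interpreted.
#'
#' @param jitter jitter SD per level, degrees (>= 4 distinct levels).
#' @param nCorrect,nTotal per-level correct and total counts.
#' @param nStarts number of multistart points.
#' @param seed RNG seed for the multistart draws.
#' @return a [PsychometricFit-class].
#' @examples
#' j <- jitterLevels()
#' p <- evaluateProbit(c(40, 12, 0.5, 0.02), j)
#' fit <- fitProbit(j, round(72 * p), rep(72, 6))
#' threshold(fit)
#' @export
fitProbit <- function(jitter, nCorrect, nTotal, nStarts = 10, seed = 171L) {
  stopIf(length(unique(jitter)) < 4,
         "need >= 4 distinct jitter levels to identify 4 parameters")
  stopIf(length(jitter) != length(nCorrect) ||
           length(jitter) != length(nTotal), "input lengths differ")
  stopIf(any(nTotal <= 0), "all nTotal must be > 0")
  stopIf(any(nCorrect < 0 | nCorrect > nTotal), "nCorrect outside [0, nTotal]")

  ## location is searched slightly beyond the tested range (a threshold far
  ## outside the stimulus ladder is not identifiable from these data)
  rng <- diff(range(jitter))
  lower <- c(min(jitter) - rng / 4, rng / 200, 0, 0)
  upper <- c(max(jitter) + rng / 4, rng * 4, 0.5, 0.5)
  pc <- nCorrect / nTotal

  ## data-informed starts (location quantiles x scale ladder, asymptotes
  ## from the observed extremes) plus seeded random restarts
  gLo <- max(0, min(0.5, min(pc) - 0.02))
  lLo <- max(0, min(0.5, 1 - max(pc)))
  det <- as.matrix(expand.grid(
    mu = quantile(jitter, c(0.25, 0.5, 0.75), names = FALSE),
    s = rng * c(1 / 8, 1 / 4, 1 / 2), guess = gLo, lapse = lLo))
  starts <- withSeed(seed,
    cbind(t(det), replicate(nStarts, runif(4, lower, upper))))
  best <- NULL
  for (i in seq_len(ncol(starts))) {
    fit <- tryCatch(
      optim(starts[, i], probitNegLL, jitter = jitter, k = nCorrect,
            n = nTotal, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 400)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  stopIf(is.null(best), "probit optimization failed from every start")
  ## polish the winner: simplex refinement, then re-project into bounds
  pol <- tryCatch(optim(best$par, function(p) probitNegLL(
    pmin(pmax(p, lower), upper), jitter, nCorrect, nTotal),
    method = "Nelder-Mead", control = list(maxit = 500)),
    error = function(e) NULL)
  if (!is.null(pol) && pol$value < best$value) {
    best$value <- pol$value
    best$par <- pol$par
    best$convergence <- 0L
  }
  best$par <- pmin(pmax(best$par, lower), upper)

  ## identifiability: flat performance across levels leaves mu/s undetermined
  pooled <- sum(nCorrect) / sum(nTotal)
  nullLL <- -sum(nCorrect * log(max(pooled, 1e-10)) +
                   (nTotal - nCorrect) * log(max(1 - pooled, 1e-10)))
  identifiable <- (nullLL - best$value) > 1e-6 && sd(pc) > 0
  if (!identifiable)
    warning("probit fit not identifiable: performance is flat across levels",
            call. = FALSE)

  best$par <- unname(best$par)
  new("PsychometricFit", mu = best$par[1], scale = best$par[2],
      guess = best$par[3], lapse = best$par[4], loglik = -best$value,
      converged = identifiable && best$convergence == 0,
      data = data.frame(jitter = jitter, nCorrect = nCorrect,
                        nTotal = nTotal))
}

#' Invert the fitted psychometric function
#'
#' Returns the jitter SD at which the fitted function predicts the target
#' proportion correct; the forward evaluation of the returned jitter
#' reproduces the target exactly (closed-form inverse).
#'
#' @param fit a [PsychometricFit-class] (or parameter vector).
#' @param targetPc target proportion correct, strictly inside the open
#'   asymptote interval `(guess, 1 - lapse)`.
#' @return jitter SD, degrees.
#' @examples
#' fit <- new("PsychometricFit", mu = 40, scale = 12, guess = 0.45,
#'            lapse = 0.02, loglik = 0, converged = TRUE,
#'            data = data.frame())
#' evaluateProbit(fit, invertProbit(fit, 0.68))
#' @export
invertProbit <- function(fit, targetPc) {
  p <- probitPars(fit)
  lo <- p[["guess"]]; hi <- 1 - p[["lapse"]]
  stopIf(any(!is.finite(targetPc)) || any(targetPc <= lo | targetPc >= hi),
         sprintf("targetPc must lie strictly inside the asymptote interval (%.4f, %.4f)",
                 lo, hi))
  p[["mu"]] - p[["scale"]] *
    qnorm((targetPc - p[["guess"]]) / (1 - p[["guess"]] - p[["lapse"]]))
}

#' Equidistant performance targets
#'
#' `n` equidistant percent-correct targets from `pcMax` down to `pcMin`,
#' inclusive; defaults reproduce the 95, 86, 77, 68, 59, 50 percent ladder
#' used to calibrate individual jitter levels.
#'
#' @param pcMax,pcMin endpoints as proportions correct.
#' @param n number of targets (>= 2).
#' @return numeric vector of proportions, decreasing.
#' @examples
#' performanceTargets()
#' @export
performanceTargets <- function(pcMax = 0.95, pcMin = 0.50, n = 6) {
  stopIf(n < 2, "need n >= 2 targets")
  stopIf(pcMax <= pcMin, "pcMax must exceed pcMin")
  seq(pcMax, pcMin, length.out = n)
}

#' Calibrate jitter levels for fixed performance targets
#'
#' Computes equidistant percent-correct targets (see
#' [performanceTargets()]) and inverts the fitted psychometric function at
#' each, yielding the individually calibrated jitter ladder.
#'
#' @param fit a [PsychometricFit-class].
#' @inheritParams performanceTargets
#' @return `data.frame` with columns `target_pc` and `jitter_deg`.
#' @export
calibrateLevels <- function(fit, pcMax = 0.95, pcMin = 0.50, n = 6) {
  targets <- performanceTargets(pcMax, pcMin, n)
  data.frame(target_pc = targets,
             jitter_deg = vapply(targets, function(p) invertProbit(fit, p),
                                 numeric(1)))
}

#' d-prime from correct/total counts
#'
#' Transforms per-level accuracy to the signal-detection sensitivity index.
#' The default convention treats the task as unbiased single-interval
#' two-alternative classification, \eqn{d' = 2\,\Phi^{-1}(PC)}; proportions
#' are first clipped to \eqn{[1/(2N),\ 1 - 1/(2N)]} so the transform stays
#' finite at ceiling or floor performance.
#'
#' @param nCorrect,nTotal counts (`nTotal > 0`).
#' @return d-prime value(s).
#' @examples
#' dprimeFromCounts(36, 72)            # chance -> 0
#' dprimeFromCounts(72, 72)            # clipped, finite
#' @export
dprimeFromCounts <- function(nCorrect, nTotal) {
  stopIf(any(nTotal <= 0), "nTotal must be > 0")
  pc <- pmin(pmax(nCorrect / nTotal, 1 / (2 * nTotal)), 1 - 1 / (2 * nTotal))
  2 * qnorm(pc)
}

#' d-prime under the yes/no convention
#'
#' Alternative convention \eqn{d' = \Phi^{-1}(H) - \Phi^{-1}(FA)} treating
#' one class (vertical) as signal; rates are clipped as in
#' [dprimeFromCounts()].
#'
#' @param nHit,nSignal hits and signal-trial count.
#' @param nFa,nNoise false alarms and noise-trial count.
#' @return d-prime value.
#' @export
dprimeYesNo <- function(nHit, nSignal, nFa, nNoise) {
  stopIf(any(c(nSignal, nNoise) <= 0), "trial counts must be > 0")
  h <- pmin(pmax(nHit / nSignal, 1 / (2 * nSignal)), 1 - 1 / (2 * nSignal))
  f <- pmin(pmax(nFa / nNoise, 1 / (2 * nNoise)), 1 - 1 / (2 * nNoise))
  qnorm(h) - qnorm(f)
}

#' Fit the log-log d-prime/jitter regression
#'
#' Ordinary least squares of \eqn{\log d'} on \eqn{\log} jitter.  Levels
#' with non-positive d-prime (performance at or below chance) have no
#' logarithm and are dropped with a warning.
#'
#' @param jitter jitter SD per level, degrees (> 0).
#' @param dprime d-prime per level.
#' @return a [DprimeRegression-class] with the t-based 95 percent CI for
#'   the slope.
#' @examples
#' j <- jitterLevels()
#' fitDprimeRegression(j, exp(0.1) * j^-0.2)
#' @export
fitDprimeRegression <- function(jitter, dprime) {
  stopIf(length(jitter) != length(dprime), "input lengths differ")
  stopIf(any(jitter <= 0), "jitter levels must be > 0")
  keep <- dprime > 0
  if (any(!keep))
    warning(sum(!keep), " level(s) with d' <= 0 dropped (no logarithm)",
            call. = FALSE)
  stopIf(sum(keep) < 3, "need >= 3 levels with d' > 0")
  m <- lm(log(dprime[keep]) ~ log(jitter[keep]))
  ci <- confint(m, level = 0.95)[2, ]
  new("DprimeRegression", beta0 = unname(coef(m)[1]),
      beta1 = unname(coef(m)[2]), sigma = summary(m)$sigma,
      ciBeta1 = unname(ci), nPoints = sum(keep))
}

#' Group-level confidence interval for the behavioral slope
#'
#' t-based 95 percent CI of the mean of per-subject d-prime regression
#' slopes (the primary mode), or the single pooled-fit CI when given one
#' regression.
#'
#' @param x a list of [DprimeRegression-class] objects (one per subject), a
#'   numeric vector of per-subject slopes, or a single
#'   [DprimeRegression-class] (pooled mode).
#' @param level confidence level.
#' @return numeric `c(lo, hi)`.
#' @export
behavioralSlopeCI <- function(x, level = 0.95) {
  if (is(x, "DprimeRegression")) return(unname(x@ciBeta1))
  b <- if (is.list(x)) vapply(x, function(f) f@beta1, numeric(1))
       else as.numeric(x)
  stopIf(length(b) < 2, "need >= 2 subjects for a group-level CI")
  m <- mean(b); se <- sd(b) / sqrt(length(b))
  m + qt(c((1 - level) / 2, 1 - (1 - level) / 2), df = length(b) - 1) * se
}

#' Per-subject d-prime regressions from a behavioral trial table
#'
#' Aggregates a trial table (as produced by [simulateBehavior()]) to
#' per-level counts within each subject (and optionally condition),
#' transforms to d-prime and fits the log-log regression.
#'
#' @param trials `data.frame` with columns `subject`, `jitter_deg`,
#'   `correct`, and optionally `condition`.
#' @param byCondition fit separately per condition.
#' @return `data.frame` with one row per subject (x condition): `beta0`,
#'   `beta1`, `sigma`, `ci_lo`, `ci_hi`, `n_points`.
#' @export
dprimeRegressionTable <- function(trials, byCondition = FALSE) {
  keys <- if (byCondition && "condition" %in% names(trials))
    interaction(trials$subject, trials$condition, drop = TRUE)
  else factor(trials$subject)
  out <- lapply(split(trials, keys), function(tt) {
    agg <- stats::aggregate(correct ~ jitter_deg, tt,
                            function(z) c(k = sum(z), n = length(z)))
    k <- agg$correct[, "k"]; n <- agg$correct[, "n"]
    fit <- fitDprimeRegression(agg$jitter_deg, dprimeFromCounts(k, n))
    data.frame(subject = tt$subject[1],
               condition = if (byCondition && "condition" %in% names(tt))
                 tt$condition[1] else NA,
               beta0 = fit@beta0, beta1 = fit@beta1, sigma = fit@sigma,
               ci_lo = fit@ciBeta1[1], ci_hi = fit@ciBeta1[2],
               n_points = fit@nPoints)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
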