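---
title: "Linking evoked potentials to behavioral sensitivity: models and methods"
author: "veplink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking evoked potentials to behavioral sensitivity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(veplink)
```

# The problem

In cue-reliability psychophysics, an observer discriminates the orientation
of a shape (here, an ellipse rendered as aligned Gabor elements) while the
reliability of the defining cues is degraded by adding Gaussian orientation
noise ("jitter") to the elements. Behavior traces out a psychometric
function of jitter; multichannel EEG recorded during the task traces out,
at every electrode and timepoint, some dependence of the evoked response on
jitter. The linking question is *where and when* the brain's response
scales with cue reliability *at the same rate* as behavior does.

`veplink` implements the full chain:

1. **Stimulus synthesis** — Gaborized ellipse displays with independently
   controlled contour and surface cue reliability (`generateDisplay()`,
   `renderDisplay()`), plus a local-density control (`densityCheck()`).
2. **Psychometrics** — four-parameter probit fitting and inversion
   (`fitProbit()`, `invertProbit()`, `calibrateLevels()`), a d′ transform
   (`dprimeFromCounts()`), and the log-log linking regression
   `log d′ = β₀ + β₁ log jitter + ε` (`fitDprimeRegression()`).
3. **Neurometrics** — rectified, z-scored single-trial amplitudes
   regressed on log jitter per channel and timepoint (`fitSlopeMap()`),
   group-level spatiotemporal cluster-based permutation inference
   (`clusterPermutation()`), and retention of the significant points whose
   slope falls inside the behavioral 95% CI (`matchBehavioralCI()`); the
   same pipeline runs response-locked via `relockToResponse()`.
4. **Peak-aligned components** — individual peak electrode/latency
   detection and a mixed-model regression of peak amplitude on jitter and
   condition with likelihood-ratio simplification
   (`findComponentPeaks()`, `fitComponentModel()`).
5. **Decoding** — per-timepoint shrinkage-LDA classification of stimulus
   orientation with activation-pattern projection and temporal cluster
   inference (`decodeTimecourse()`, `activationPatterns()`,
   `temporalClusterTest()`).
6. **Synthetic data with ground truth** — seeded generators for observer
   behavior and multichannel epochs with planted effects
   (`simulateBehavior()`, `simulateEpochs()`, `makeMontage()`), used
   throughout the test suite for parameter-recovery and calibration
   checks.

All stages are deterministic under a fixed seed, and `runPipeline()` ties
them into one seeded, provenance-stamped run.

# Stimulus model

A display is a `displayPx × displayPx` field (default 1000 px, 62.5
px/deg) holding 590 non-overlapping Gabor elements: 43 on the outline of
an ellipse (major axis 10.2 deg, axis ratio 1.2), 150 inside it, and 397
in the background. The ellipse center is displaced by 0.69 deg along a
randomly chosen half-meridian so that fixed-location strategies are
uninformative. Contour elements sit at equal arc-length spacing along the
outline and take the local tangent orientation; surface elements take a
common base orientation (−45° from vertical); cue reliability is degraded
by adding i.i.d. Gaussian orientation jitter (SD in degrees) to the active
cue's elements. Inactive regions are uniformly random, except in the
surface-only condition where contour and background elements are fixed at
+45°. Orientation convention: degrees from vertical, positive clockwise;
stored orientations are left unwrapped so jitter draws can be recovered
exactly (orientations are equivalent modulo 180°).

**Element placement.** Surface and background elements are placed by
dart-throwing with a minimum center-spacing constraint (default 30 px),
drawing from one homogeneous proposal over the whole display and
interleaving the two region quotas in random order. The interleaving
matters: points placed late in a packing land in small gaps and therefore
sit closer to their neighbors, and if one region fills last it becomes
systematically denser in nearest-neighbor terms. The default spacing makes
the mean distance to the four nearest neighbors ≈40 arcmin, consistent
with the session-level mean center-to-center distance implied by the
design (√(display area / 590) ≈ 39.5 arcmin).

**Density control.** `densityCheck()` computes, for every element, the
mean Euclidean distance to its four nearest neighbors (searched over all
elements by default; a within-region switch is provided) and compares the
three region pairs with Welch's unequal-variance t-test at α = 0.1; a
display is accepted when no pair differs. Two structural facts are worth
knowing. First, with ~150 and ~397 elements per region the test resolves
mean differences of about one arcmin. Second, the fixed design itself
produces differences of that order: background elements own the display
edge, where missing outside-neighbors inflate nearest-neighbor distances
by ~2 px on the region mean, and the fixed counts vs region areas imply a
few-percent raw density imbalance. Consequently default-geometry displays
usually *fail* the filter; this is the filter working as specified, not an
error. Its statistical behavior is validated in the test suite on
label-exchangeable displays (regions placed by one process, labels
permuted), where the family-wise rejection rate sits between the per-test
α and 1 − (1 − α)³ as it must for three correlated tests.

**Rendering.** Each element is an oriented sine-wave grating (3 cycles per
0.7 deg) at 50% Michelson carrier contrast under a circular Gaussian
envelope (SD 3.8 arcmin), drawn additively on a mid-grey background and
clipped to [0, 1]; carrier phase is uniform-random per element (seeded),
with a peak-aligned option for testing. Uniform pixel-noise masks come
from `makeNoiseMask()`.

# Behavioral model

Accuracy at jitter level $j$ follows the four-parameter probit

$$P(\text{correct} \mid j) = g + (1 - g - l)\,\Phi\!\left(\frac{\mu - j}{s}\right),$$

with guess rate $g$ and lapse rate $l$ free in $[0, 0.5]$. The
*threshold* is the inflection point $\mu$ (performance midway between the
asymptotes) and the *slope* is the gradient there,
$-(1-g-l)\,\phi(0)/s$. Fitting is binomial maximum likelihood with a
bounded quasi-Newton optimizer started from a data-informed grid
(location quantiles × scale ladder × asymptotes from the observed
extremes) plus seeded random restarts, and polished with a simplex pass;
the test suite verifies the optimum against brute-force grid search. The
location parameter is searched over the tested jitter range ±25% — a
threshold far outside the stimulus ladder is not identifiable from these
data, and unbounded search lets near-flat datasets wander to arbitrarily
large locations. Flat datasets are flagged `converged = FALSE` rather
than silently fitted.

Two properties of this estimator deserve emphasis. With the guess rate
free and a true observer whose guess sits at the boundary (0.5, as in a
two-alternative task) the ML threshold is biased upward at realistic trial
counts: the recovery simulations in the test suite measure a mean bias of
about +2 deg at 72 trials/level, driven by a heavy right tail of near-flat
realizations whose extreme fits are genuine global ML optima. This is a
property of free-guess ML fitting under these conditions, not of the
optimizer. Second, the closed-form inverse
(`invertProbit()`) round-trips exactly, so inverse-function calibration of
jitter levels at fixed performance targets (95…50% correct in six
equidistant steps, `performanceTargets()`) is exact by construction.

**d′ and the linking regression.** Per-level accuracy is re-expressed as
$d' = 2\,\Phi^{-1}(PC)$ — the unbiased single-interval two-choice
convention; a yes/no variant $\Phi^{-1}(H) - \Phi^{-1}(FA)$ is available
(`dprimeYesNo()`). Proportions are clipped to $[1/2N,\ 1 - 1/2N]$ so the
transform stays finite; levels with $d' \le 0$ have no logarithm and are
dropped with a warning. The linking model is ordinary least squares of
$\log d'$ on $\log j$; its slope $\beta_1$ carries the behavioral
sensitivity to cue reliability, and the group-level 95% CI of the mean of
per-subject slopes (`behavioralSlopeCI()`; a pooled-fit variant is also
accepted) is the band against which EEG slopes are matched.

# Synthetic data

The generators exist so every stage can be tested against known ground
truth; their defaults emulate the study conditions.

* `observerSpec()` / `simulateBehavior()`: blocks of 432 constant-stimuli
  trials equally divided over six jitter SDs (1…65 deg; 72
  repetitions/level/block), two blocks per condition (1728 trials),
  balanced stimulus orientation, Bernoulli correctness from the
  condition's probit, lognormal RTs targeting a ~820 ms mean, ISIs from
  {500, 550, 600, 650} ms.
* `makeMontage()`: a Fibonacci spiral on the upper unit hemisphere
  (default 128 channels) with distance-threshold adjacency; the default
  threshold (median 6th-nearest-neighbor distance) keeps the median
  neighbor count in the 4–10 range typical of sensor-space cluster tests.
* `eegSpec()` / `simulateEpochs()`: epochs are spatially correlated
  Gaussian noise (exponential kernel on inter-electrode distance plus
  white sensor noise) plus (i) evoked components — a topography times a
  Gaussian time kernel near 90/307/402 ms, with a per-subject latency
  offset drawn once per subject (latency SDs 11.1/10.9/27.9 ms), (ii) a
  planted effect adding `amplitude + slope·log(jitter)` times a
  topography inside a time window (default: 10 electrodes, 380–440 ms,
  negative slope), and (iii) a class signal whose sign follows stimulus
  orientation (default window 320–445 ms).

Three design choices make the planted values exactly recoverable by the
documented analysis. Planted topographies are zero-sum across channels, so
average-referencing passes them untouched. Planted amplitudes are stated
in z-units of the *analysis window*: pooled z-scoring divides by the SD of
whatever window is analyzed, so the generator calibrates its scale on
`calibrationWindowMs` (default −100…500 ms) and accounts for the noise
variance left after average-referencing. And the planted effect acts on a
signed amplitude whose magnitude decreases with jitter while staying well
above the noise floor (the default margin keeps the weakest-reliability
magnitude ≳2.5 noise SDs), so rectification preserves the slope: the
derivative of $E|\mu + \varepsilon|$ with respect to $\mu$ is
$1 - 2\Phi(-\mu/\sigma)$, which is ≈1 only when $\mu/\sigma$ is large.

What the generator does *not* emulate: ocular/muscular artifacts (the
artifact-rejection and ICA steps of a real pipeline have no synthetic
counterpart and would sit between epoching and preprocessing), temporal
autocorrelation of the background EEG (noise is white in time; spatial
correlation only), 1/f spectral shape, and biophysically realistic forward
models. Passing recovery tests therefore demonstrates the *analysis* is
correct and calibrated, not that it is robust to artifacts.

# The neurometric linking analysis

`preprocessEpochs()` applies, in fixed order: average reference (subtract
the cross-channel mean at each trial and timepoint), z-scoring with one
mean/SD per subject pooled over all trials × channels × timepoints, and
rectification. Each stage is independently toggleable; the pooled
z-scoring is one reading of "z-scored across trials and electrodes" and
the switch exposes the choice.

`fitSlopeMap()` regresses single-trial rectified amplitude on **log**
jitter at every (channel, timepoint) within subject. Log jitter is the
default predictor in both the behavioral and the EEG regression — the
CI-matching step presumes commensurate slopes — with raw jitter as an
option; a level-means mode (six points per fit) has the same expectation
with different degrees of freedom. The slopes come from the closed-form
centered cross-product and are verified against per-point `lm()` in the
tests.

`clusterPermutation()` computes a one-sample t across subjects at every
point, thresholds two-tailed at the cluster-forming quantile (default
p < 0.01), and clusters suprathreshold points under montage adjacency ×
temporal contiguity with consistent sign; the cluster statistic is the
mass (sum of |t|). The null is random per-subject sign flips; per
permutation the maximum cluster mass over *both* signs is recorded, and
cluster p-values use the add-one rule `(1 + #null ≥ obs)/(1 + nPerm)`.
Comparing against the tail-pooled maximum controls the two-tailed
family-wise error at `alphaCluster` directly (the sign-flip null is
symmetric, so per-tail and pooled conventions agree in distribution);
type-I calibration is verified by Monte Carlo in the acceptance suite.
Note the resolution floor: flipping *all* subjects' signs reproduces |t|
exactly, so with $n$ subjects no cluster can achieve p below ≈ $2/2^n$ —
p ≤ 0.01 needs 11+ subjects (the study has 16). The forming threshold and
the cluster-level α are deliberately separate knobs: the source analysis
states a single "p < 0.01" that can be read as either, and both are
recorded in the result object.

`matchBehavioralCI()` retains, inside each significant cluster, the points
whose cross-subject mean EEG slope lies within the behavioral 95% CI; a
cluster-average variant retains whole clusters by their mean slope. Both
readings of the retention rule are computed because the source analysis
admits both; the point-wise rule is the default. The mask is a subset of
the significant clusters by construction.

`relockToResponse()` re-centers each trial on stimulus onset + RT
(nearest sample; default window −1000…0 ms), dropping trials whose window
leaves the epoch with a logged count. With the session's RT spread
(~120 ms SD), a stimulus-locked planted effect smears across
response-locked time: single-trial regression then sees the effect at any
given point in only a minority of trials, the rectified slope shrinks
several-fold, and the match mask comes out empty at matched power — the
response-locked null pattern the analysis is designed to distinguish.

# Peak-aligned components

For each subject, `findComponentPeaks()` averages all trials, selects
within each search window the electrode with the highest activity
(largest absolute mean amplitude by default; signed modes for
fixed-polarity components), takes the latency of the extremum there, and
reads out per-condition × per-level mean amplitudes at that electrode and
latency. Window-boundary extrema are flagged and excluded from modeling
rather than trusted — the same logic under which a component identifiable
in only half the observers would be dropped. Default search windows
(60–140, 250–350, 350–480 ms) are configuration, not claims.

`fitComponentModel()` fits `amplitude ~ log(jitter) * condition +
(1 | subject)` by maximum likelihood (ML, not REML, so likelihood-ratio
tests on fixed effects are valid) and simplifies backward — drop the
interaction, then condition, then jitter — stopping when a drop
significantly worsens fit at α = 0.05. Random intercepts only: sixteen
subjects × six levels rarely identify slope variance. One property of the
backward chain worth knowing: selecting the intercept-only model under
pure noise requires three consecutive non-significant LRTs, so its
specificity is ≈ 0.95³ ≈ 0.86, not 0.95; the simulation tests assert the
chain's behavior at that level.

# Decoding

`balanceClasses()` equalizes the orientation classes by seeded random
down-sampling of the majority class, once, before cross-validation — as
the source procedure is written. (Balancing inside each training fold
would be the leakage-free alternative; with the generator's balanced
designs the distinction is immaterial.) `estimateCommonShrinkage()`
computes the oracle-approximating shrinkage coefficient of the channel
covariance at every timepoint, averages over timepoints within subject and
then over subjects; the shrinkage target is the scaled identity (average
eigenvalue), and for data whose covariance is itself near-spherical the
estimator correctly returns γ → 1 (shrinking fully toward a correct
target). `decodeTimecourse()` trains, at each timepoint, an LDA on the
channel vector with pooled within-class covariance shrunk as
$\Sigma_\gamma = (1-\gamma)\hat\Sigma + \gamma\,(\mathrm{tr}\,\hat\Sigma/C)\,I$,
under stratified 10-fold cross-validation (fold class proportions within
one trial); weights and activation patterns come from the full-data fit.
`activationPatterns()` projects weights through the data covariance
(pattern = Σw, unit maximum absolute value), the standard forward-model
reconstruction that makes classifier weights interpretable as scalp
topographies. `temporalClusterTest()` applies the same sign-flip
cluster-mass machinery in one dimension to per-subject accuracy traces
against chance.

One empirical caution encoded in the tests: cross-validated accuracy under
label shuffling concentrates slightly *below* chance (label noise
anticorrelates training and test folds), with spread wider than a naive
binomial band; the chance-level tests use CV-appropriate bounds.

# Numerical choices and reproducibility

* Every stochastic step takes an explicit integer seed; seeded runs are
  bit-reproducible, and the RNG state of the caller is restored.
  Derived seeds stay inside the 32-bit range.
* The epochs container is language-neutral: `metadata.json` + row-major
  little-endian float64 `data.bin` (trial × channel × time) +
  `trials.tsv`; reads validate version, dimension order and byte counts
  and fail with classed errors rather than returning misaligned data.
* `runPipeline()` stamps every output table with an MD5 hash of the
  configuration (excluding the output location) plus the seed, and writes
  a `provenance.json`.
* Permutation p-values use the add-one convention, never zero.
* The probit inverse and the log-log regression are closed-form; the
  probit forward model clips probabilities at 1e-10 for likelihood
  evaluation.
* Test and acceptance simulations are scaled to single-CPU sizes chosen
  as design points: cluster-test calibration runs 200 null datasets of 16
  subjects × 32 channels × 120 timepoints at 500 permutations; linking
  recovery uses 16 subjects × 864 trials × 32 channels; decoding checks
  use 8 subjects × 216 trials with 1000-permutation temporal cluster
  calibration. The statistical bands asserted are computed at the sizes
  used.

# Known limitations

* The density filter's verdict on default-geometry displays is dominated
  by structural edge effects (discussed above); practitioners who need
  accepted displays at α = 0.1 should treat the spacing and geometry as
  free parameters, or restrict the neighbor search within regions.
* ML probit thresholds with a free guess rate are upward-biased at these
  trial counts (≈+2 deg); group comparisons inherit that bias in common.
* The EEG noise model is white in time; temporal cluster extents on real
  data (autocorrelated noise) will differ from synthetic calibrations.
* `fitComponentModel()` requires near-complete subject × condition ×
  level cells (≤20% missing) and will refuse sparser designs.
* Response-locked analyses inherit the stimulus-locked epoch span: trials
  with extreme RTs are dropped, and the drop count should be checked
  against the session's RT distribution.
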