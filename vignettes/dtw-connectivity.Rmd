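---
title: "Measuring functional connectivity with Dynamic Time Warping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring functional connectivity with Dynamic Time Warping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtwfc)
```

## The problem and the model

Conventional resting-state functional connectivity summarizes the
relationship of two BOLD time series by their zero-lag Pearson
correlation. That statistic assumes the coupling is stationary and
synchronous. Real couplings are neither: connectivity fluctuates on
scales of seconds to minutes, and between-network relationships
("anticorrelations" between default-mode and task-positive nodes)
typically appear as intermittent couplings with time lags of tens of
seconds rather than as a stable sign flip.

`dtwfc` measures connectivity with the Dynamic Time Warping (DTW)
distance instead. For two series $x_1, x_2$ of lengths $l_1, l_2$, the
accumulated-cost matrix is

$$
D(i,j) = (x_1(i) - x_2(j))^2 +
  \min\{D(i-1,j-1),\, D(i-1,j),\, D(i,j-1)\},
$$

with the obvious first-row/first-column edge cases and
$D(1,1)=(x_1(1)-x_2(1))^2$; the distance is $\sqrt{D(l_1,l_2)}$. The
minimum runs over monotone alignment paths from $(1,1)$ to
$(l_1,l_2)$, so samples may be matched across a time offset; a
Sakoe–Chiba band $|i-j| \le w$ caps that offset at the *warping
window* $w$, specified in seconds and converted by the sampling
interval TR (rounding half away from zero). Because the local cost is
a squared difference and inputs are z-scored (population 1/N
convention throughout, so correlation is exactly the inner product of
z-scores over N), a small DTW distance means the two series trace the
same trajectory up to time shifts within the window.

Two baselines are implemented through the same interface: zero-lag
Pearson correlation, and maximal-lag cross-correlation (the signed
coefficient of the largest absolute overlap-renormalized correlation
over integer lags up to the window; the sign is kept because genuinely
anticorrelated pairs must be able to report a negative value).

### From distances to similarities

DTW distances grow with series length and have no fixed upper bound,
so over one analysis unit — all voxels of a seed map, or all pairs of
a connectivity matrix — distances are negated and demeaned:
$s_i = \overline{d} - d_i$. Unconnected pairs then scatter around
zero, strong connections have large positive similarity, and the usual
one-sample t machinery applies. The transform is order-reversing and
affine; raw distances are always retained alongside.

The demeaned null is centred exactly and is unimodal, but it is not
perfectly Gaussian at fMRI-scale windows: with $w$ about one sixth of
the series length the path minimisation clips the lower tail of the
distance distribution more gently than the upper one, leaving a mild
right skew (skewness 0.35–0.6 in our surrogate batches) that a
formal normality test detects at 500 samples even though the
distribution's core looks normal in a histogram. With short windows
(a few samples) the skew is negligible and Shapiro normality holds.
This matters only for inference that relies on exact tail shape; the
t statistics used here depend on the centring and the finite variance.

## Warping-window choice

The window should exceed the longest time lag the analysis is meant to
absorb.

* Whole-brain resting-state analysis: 100 s. The slowest retained
  fluctuations (~0.01 Hz) can express anticorrelation as a
  half-period delay of ~50 s, with fluctuation on top; 100 s covers
  it.
* Detecting only tightly synchronous coupling: a short window (4 s =
  2 samples at TR 2 s) makes DTW behave like zero-lag correlation.
* The common-noise experiment (below) couples two anti-phase 0.08 Hz
  sinusoids: the relevant lag is the half-period 6.25 s, so the
  window is 8 s, the smallest multiple of TR above it. A much larger
  window would be counterproductive there: elastic matching shrinks
  the *null* pairs' distances faster than the signal pair's, eroding
  the contrast. This is the general trade-off: the window buys lag
  tolerance at the price of null discrimination, so it should be
  matched to the longest lag of scientific interest, not maximized.

## Signal conditioning

The chain is fixed in this order: nuisance regression, then band-pass
filtering, then z-scoring. Confounds are the six head-motion
parameters (when available), mean WM and CSF series and the first five
principal-component series of each tissue, and optionally the global
(brain-mean) signal; the residual is an ordinary least-squares
residual, orthogonal to every confound. The band-pass retains roughly
0.009–0.08 Hz: a DCT-basis high-pass of order 9 (the order is the
parameter, not the implied cutoff — for a 600 s run the order-9 basis
edge is 9/(2·600) = 0.0075 Hz, slightly below the conventionally
quoted 0.009 Hz, and the constant term is counted extra) followed by a
12th-order Butterworth low-pass applied forward and backward. The
bidirectional pass doubles the effective magnitude order and zeroes
the phase; coefficients come from `signal::butter()`, while the
application uses odd-extension padding with steady-state initial
conditions so that a constant series passes through exactly (DC gain
1 to machine precision) and no edge transients leak into the series.

## Simulation experiments

**Transient interactions.** Surrogate signals are white Gaussian noise
passed through the same band-pass and z-scored. A transient
interaction is planted by overwriting a window of one surrogate with a
segment of another at a chosen delay; re-z-scoring keeps unit variance
and makes the expected zero-lag correlation of a zero-delay
interaction approximately the shared fraction L/T. Significance is
judged against empirical nulls from independent surrogate pairs (5th
and 95th percentile for correlation, 5th percentile of distances for
DTW). Over a delay × length grid (0–100 s by 4 s; 60–600 s by 60 s by
default), correlation and short-window DTW detect only short-delay
interactions, while 100 s-window DTW detects long-delay interactions
whenever the shared segment is long enough. One caveat the grid
resolution makes visible: the retained band has a positive
autocorrelation lobe of ~9 s, so a shared segment shifted by one or
two 4 s grid steps still carries genuine zero-lag correlation;
"synchronous-only" for correlation means "within the autocorrelation
width", not literally the zero column.

**Common noise.** Two anti-phase 0.08 Hz sinusoids receive independent
band-passed noise calibrated by bisection (tolerance 0.005 on the
batch-mean correlation) so the pair correlates at −0.86; a single
band-passed common signal is then mixed in as
$(1-\alpha)x_i + \alpha c$ with $\alpha$ up to 0.5, and both metrics
are tracked against their nulls. Correlation drifts to zero and loses
significance; the DTW distance (8 s window, see above) stays below its
null's 5th percentile over the whole range.

## The synthetic fMRI generator

`synth_fmri()` builds a small 4D dataset with known structure: each
network's voxels share a band-limited latent source (optionally a
delayed copy of a master source, planting the lagged couplings DTW is
built to capture, or a negated copy for zero-lag anticorrelation, with
per-network coupling weights), plus white voxel noise and an additive
global signal. WM and CSF blocks carry noise only — deliberately
excluded from the global component, because tissue-mean confounds
would otherwise absorb the global signal in *both* preprocessing
pipelines and the with/without-GSReg contrast under study would
vanish. The generator emulates the statistical structure the analyses
assume — band-limited sources, lagged couplings, additive global
noise — and nothing anatomical: no hemodynamic response model, no
spatial smoothness, no motion, no physiological quasi-periodicity.
Passing tests on these fixtures validates the estimators' behaviour
under the stated statistical model, not performance on real scanners.

The GSReg sensitivity experiment (`gsr_dubious_experiment()`) uses a
fixture with four populations beside a majority of null gray-matter
voxels: the seed's network; a 30 s delayed copy; a weak negated copy
whose zero-lag anticorrelation cancels against the shared global
component and surfaces only after GSReg (zero-lag correlation's
characteristic "dubious" regime); and a stronger negated copy whose
anticorrelation sits below the maximal-lag search's noise ceiling
without GSReg but clears it with GSReg (cross-correlation's dubious
regime, half the size of correlation's, emulating the relative extent
of the two phenomena in real data). Per metric, run-level seed maps
feed fixed-effect t maps (t = mean/(sd/√n), df = n−1, two-sided,
Benjamini–Hochberg FDR), and pipeline-unstable voxels are counted:
significant-and-negative with GSReg but not significant without, for
the signed metrics; significant under exactly one pipeline (XOR) for
DTW. The expected ordering — DTW fewest, then cross-correlation, then
correlation — reproduces on essentially every fixture seed.

## Classification

Connectome features are the 4005 upper-triangle entries (row-major)
of a 90-ROI connectivity matrix; DTW matrices pass through the
similarity transform before vectorization. The classifier minimizes
$(1/N)\lVert y - X\theta \rVert_2^2 + \lambda \lVert \theta \rVert_1$
with an unpenalized intercept by cyclic coordinate descent
(soft-threshold updates $S(\rho_j, \lambda/2)$ on standardized
features; convergence when the largest per-sweep change falls below
1e−6, capped at 10⁴ sweeps; an active-set iteration between full
sweeps accelerates the path without changing the solution).
Evaluation is nested leave-subject-out cross-validation: all runs of
one subject are held out; an inner leave-subject-out pass selects λ
from 25 log-spaced values in [0.0005, 0.5] (ties prefer the larger,
sparser λ); the model is refit and the held-out runs are predicted by
thresholding the regression output at 0.5. Standardization parameters
always come from the training rows only.

Two nulls are provided. The coin-flip threshold draws iid
Bernoulli(½) label vectors and takes a percentile of their accuracy
against the true labels — equivalently a Binomial(N, ½) quantile.
The permutation threshold reruns the entire nested CV on
subject-level label permutations. These are *not* interchangeable:
held-out runs of a subject are predicted jointly, so CV null
accuracies are over-dispersed relative to independent guessing, and
permutation thresholds sit above the coin-flip threshold. The
coin-flip band is therefore an anticonservative screen and the
permutation test the honest reference. A related degeneracy is worth
knowing: with an exactly balanced label split, the fully shrunk
model's intercept lands on the wrong side of 0.5 for every held-out
subject and the null CV accuracy collapses well below chance
(anti-learning). Real cohorts are rarely exactly balanced; the
synthetic dataset generator defaults to an 11/9 split of 20 subjects
for this reason.

## Numerical choices and conventions

* Seconds→samples conversion rounds half away from zero.
* Backtracking ties prefer the diagonal, then the vertical
  predecessor — one canonical path.
* Distances use band-only storage (memory ∝ l·(2w+1)); the full
  matrix is materialized only for path extraction and plots.
* Unequal lengths are allowed when the band can reach the corner
  (w ≥ |l1−l2|); an infeasible band is an error, not an NA.
* `max_lag_xcorr` renormalizes each lag's overlap, skips overlaps
  shorter than 3 samples with a warning, and breaks ties toward the
  smaller |lag|, then the positive lag.
* Degenerate inputs fail loudly: constant series cannot be z-scored
  or correlated; single values cannot be demeaned into similarities;
  zero-variance voxels get t = ±∞ (or 0 when the mean is also zero)
  and are flagged.
* Paired map comparisons include voxels significant in at least one
  of the two maps (union policy; intersection and all-voxel variants
  are available), with non-significant values retained inside the
  union.
* All generators are seed-deterministic; every CLI run writes a
  manifest (resolved configuration, package version, seed) and
  re-running with the same configuration reproduces the numerical
  artifacts byte for byte.

## Problem sizes used in the test suite

The suites run on one CPU in a few minutes: surrogate experiments use
300-sample series (600 s at TR 2 s) with 200-pair nulls and 5
repetitions per grid cell; the GSReg experiment uses 8×8×4 fixtures
with 150 volumes and six runs per pipeline over ten fixture seeds; the
classifier recovery uses 20 subjects × 5 runs × 300 features, with
null calibration at 12 subjects × 3 runs × 100 features over twelve
replicates. These sizes are the package's chosen simulation scale;
all of them can be raised through the exported parameters.

## Known limitations

* DTW lag absorption carries O(shift) boundary costs at the matrix
  corners: a lagged copy is recognized far better than chance, but a
  short series with a large lag keeps a noticeable residual distance.
  Detection of a 30 s lag is reliable at 600 s series length, marginal
  at 300 s.
* The long-window similarity null is mildly right-skewed (above);
  percentile thresholds are taken from the empirical null rather than
  from a fitted Gaussian for this reason.
* DTW is sign-blind: a negated coupling (zero-lag anticorrelation
  without a lag structure) looks like noise to it. The
  "anticorrelations" of interest in resting-state data behave as
  lagged positive couplings, which is what the metric is built to
  capture; where the sign matters, correlation must be consulted
  alongside.
* The distance scale depends on series length; cross-experiment
  comparisons need the length-normalized variant or a per-experiment
  null.
* Computation is O(l·w) per pair rather than O(l): whole-brain maps
  cost minutes, not seconds, though the per-voxel loop is a single
  C++ kernel call.
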