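---
title: "Methods: design, simulation and inference in emogonogo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: design, simulation and inference in emogonogo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the models and
estimators it implements, the parameters that matter, what the synthetic
data generator does and does not emulate, and the numerical choices made
where the design was genuinely open. It states no empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## 1. The task design model

A session is four 330-s runs of 2-s trials: 84 neutral-go, 80 aversive-go,
20 neutral-nogo and 20 aversive-nogo trials (Go:NoGo 4:1 to make the Go
response prepotent), each run opening with a neutral-go trial. The 84/80
asymmetry is reproduced literally: an 80/80/20/20 core is split evenly over
runs and one neutral-go is prepended per run.

**Inter-trial intervals.** ITIs are drawn from {2, 4, 6} s at 30/40/30,
allocated by largest remainder (204 trials give exactly 61/82/61 and a mean
of exactly 4 s). Two balance constraints interact here. The session-level
mix must be 30/40/30, *and* no trial type may see a biased ITI history
(otherwise BOLD non-linearity would confound type with preceding interval).
These cannot both hold if "unbiased" is read as *equal thirds* per type:
thirds across four types would force a ~1/3–1/3–1/3 session marginal,
contradicting 30/40/30. The package therefore balances each type's
preceding-ITI distribution to the *same 30/40/30 proportions* as the
marginal — the counterbalancing that actually removes the type × ITI
confound — allocating per type by largest remainder and reconciling the
table so every cell is within one trial of its proportional share while the
column sums equal the session allocation exactly. `checkSessionDesign()`
re-derives all of this.

**Transition balance.** First-order counterbalancing aims at transition
counts proportional to marginal frequencies (n_prev × n_next shares):
uniform transition counts are unattainable when NoGo trials are 5× rarer
than Go trials. Sequences are built by a randomized greedy pass (pick the
feasible next type with the lowest relative fill of its transition cell,
preferring types with more trials remaining) and the best of `attempts`
(default 20) constructions by summed squared deviation is kept. The
achieved deviation is recorded in the design metadata and verified by the
checker rather than asserted against an absolute bound, because the
attainable minimum depends on the counts.

**Run padding.** Trials plus ITIs underfill 330 s; the slack is split
between leading and trailing fixation (configurable `padSplit`, default
half), rounded to the volume grid. ITI loads are rebalanced across runs (by
swapping ITIs within a trial type, preserving all counts) so each run keeps
enough leading fixation to cover the 6 discarded lead-in volumes.

**Stimulus selection** ranks images by Euclidean distance in
\[arousal, valence\] space within valence strata (aversive: valence ≤ 3.6,
target \[9, 1\]; neutral: 3.6 < valence < 6.4, target \[1, 5\]); ties break
lexicographically by id so selection is deterministic.

## 2. The synthetic-data generator

The generator exists so every downstream stage can be tested against known
truth; its defaults mirror the study conditions it emulates.

**Cohort.** Latent (ARBS, BIS) pairs come from a bivariate Gaussian with
empirical-correlation matching at the target r = 0.78, means/SDs 15.6/4.6
and 67.6/16.1. Exactly `nHigh` (default 10 of 21) participants land in the
high-risk stratum: scores are mapped rank-preservingly into \[17, 30\] and
the rest into \[9, 13\], mirroring the sampled population's bimodal break —
mid-range ARBS values (14–16) never occur by construction. The achieved
post-discretization correlation is recorded as an attribute rather than
asserted, since clipping and rounding perturb it. BIS totals decompose into
six subscale sums proportional to the sample subscale means, respecting
each subscale's item-count bounds.

**BOLD signal.** Each in-mask voxel carries
`baseline + Σ_trials a(region, type, scores) · h(t − onset)` with `h` the
canonical double-gamma HRF (peak delay 6 s, undershoot delay 16 s, unit
dispersions, peak:undershoot 6:1 — the conventional parameterization of the
difference-of-gammas family; the peak falls near 5 s). Amplitudes are
per-region × per-type, plus per-region slopes times the participant's
mean-centred ARBS/BIS scores — the ground truth that recovery tests check.

**Noise.** White Gaussian innovations are smoothed spatially per volume
(separable Gaussian, variance renormalized), then AR-filtered recursively
over time within run (coefficients up to lag 10, stationarity enforced).
Optional low-frequency drift (linear + one-cycle sinusoid, random voxel
loadings) and six motion-like smooth nuisance timecourses with random
spatial loadings complete the model; the motion timecourses are returned so
the GLM can (and by default does) include them as nuisance columns. Each
run carries 6 lead-in volumes flagged for discard so the pipeline exercises
the discard rule.

**What it does not emulate:** scanner artifacts (spikes, inhomogeneity),
slice-timing, non-stationary spatial smoothness, physiological noise
spectra, or anatomically realistic geometry (the atlas fixture is a Voronoi
partition of an ellipsoid — convex cells guarantee contiguous regions).
Passing tests therefore demonstrate correctness of the estimators under the
assumed model, not robustness to everything real data can do.

## 3. First-level estimation

The FIR design uses 7 impulse predictors per type at 2-s spacing (timepoint
k spans 2(k−1) s after onset), an optional collapsed error set, and per-run
nuisance blocks. Autocorrelation is estimated at lags 1–10 per slice by
pooling residual cross-products over the slice's voxels within runs — the
pooling stabilizes the estimate at the cost of assuming slice-wise
homogeneity. Levinson–Durbin converts the pooled ACF to AR coefficients,
stopping early if a reflection coefficient approaches ±1 (reduced-order
fallback). Whitening applies the inverse Cholesky factor of the AR model's
Toeplitz correlation per run to data and design; with a zero ACF the fit is
exactly OLS, and on ≤500-voxel instances it matches a dense
(X′V⁻¹X)⁻¹X′V⁻¹y oracle to 10⁻⁶ (tested).

Contrast effects average the FIR betas at timepoints 3–4 (4 and 6 s, the
hemodynamic peak window). Averaging, not summing, keeps effects in
amplitude units; `combine = "sum"` is available. One bias is inherent and
worth knowing: the 7-point FIR window truncates the undershoot tail of the
response, so even noiseless recovery is good to ~1%, not machine precision
— the recovery tests assert the 1% bound.

Degrees of freedom are volumes − rank(design), recorded per fit. The
second level reports its own analytic df (n − rank) with an override
accepted, and computes t quantiles rather than hard-coding printed critical
values.

## 4. Group inference and cluster calibration

Per voxel, the nine maps regress first-level effects on a column of ones,
or ones plus one mean-centred score. The mixed-effects mode weights by
1/(first-level SE² + τ²) with τ² from a method-of-moments estimate floored
at zero — a deliberate simplification of spatially regularized EM schemes,
which are out of scope. The basic OLS mode exists because the permutation
calibrator needs thousands of refits.

Cluster-extent calibration is implemented twice:

- **Permutation**: trial-type labels are permuted independently within each
  participant (onsets fixed), the first level is refit, a basic OLS second
  level is computed, and the maximum same-sign suprathreshold cluster size
  is pooled over all nine maps (per-map calibration optional). The extent
  is the smallest size whose null exceedance rate is ≤ α.
- **Monte Carlo**: Gaussian white noise on the mask's bounding grid,
  smoothed to the target FWHM, variance-renormalized in-mask, thresholded
  two-tailed at the normal quantile. Residual smoothness feeding this comes
  from the Gaussian-ACF model on first spatial differences
  (σ² = −1/(4 ln ρ₁) in voxel units per axis, geometric-mean FWHM across
  axes), averaged over residual volumes; a 9-mm kernel is recovered within
  10% (tested).

On matched stationary synthetic null data the two calibrators agree within
25% (tested). On real data they can diverge widely — non-stationary
residual smoothness violates the Monte Carlo model's core assumption, which
is why the permutation route is the principled default and the Monte Carlo
route is best treated as a fast approximation. Published AlphaSim-style
thresholds for particular datasets depend on that dataset's mask geometry
and smoothness estimate and should not be expected to transfer.

Default connectivity is faces-only (6-connectivity), configurable to 18 or
26; positive and negative excursions are clustered separately. Timecourse
QA refits the FIR model to cluster-mean timecourses and correlates the
across-type mean 7-point response with the canonical double-gamma sampled
at the FIR timepoints; the default cutoff 0 (any positive resemblance
passes) replaces what was historically a visual inspection, and flat
timecourses are flagged indeterminate rather than scored.

## 5. The correlation-pattern similarity statistic

With R regions and C contrasts (default 26 × 3 = 78 columns), an
instrument's pattern is the vector of Pearson correlations between
participants' per-region mean contrast values and their scores. Similarity
is

S(a, b) = 1 − ‖a − b‖² / L,

one minus the *mean squared* entrywise difference. The defining identities
— S = 1 iff identical, S = 0 for all-ones vs all-zeros, range \[−3, 1\] for
correlation-valued entries — pin down the squared form: a literal
Euclidean-distance-over-L reading cannot reach 0 for the all-ones/all-zeros
pair at L = 78 (it is confined to \[1 − √78/78, 1\] ≈ \[0.887, 1\] there),
so the squared form is the default and the literal form is kept as
`form = "euclidean"` for comparison.

The split test stratifies by risk class (low/high; a mid stratum is
balanced across groups if present), splits each stratum as evenly as
possible without replacement — odd members go to whichever group is behind,
coin-flipped on ties, so total group sizes differ by at most one — and
computes instrument A's pattern from group 1 and B's from group 2. A
with-replacement variant exists (`replace = TRUE`) for users who want a
bootstrap flavour, but plain splitting is the default: the statistic
compares *independent* half-cohorts, and resampling with replacement would
blur that interpretation. Constant columns or scores within a group are an
error, never a silent zero.

## 6. Problem sizes, tolerances and degenerate inputs

- Test-suite simulation sizes are the package's own desk-scale choices:
  10×10×6–20×20×12 grids, 6–21 participants, 100–3000 calibration
  iterations; the acceptance script uses the full 82,244-voxel brain-like
  mask with 1500 Monte Carlo iterations. Statistical assertions use
  binomial confidence bands at those sizes.
- Resampling p-values are floored at 1/n_iter and never reported as 0.
- The percentile residual bootstrap is asymptotic; its type-I error is
  checked at n = 40, where the finite-sample inflation visible at n ≈ 15
  has decayed into the nominal band.
- The bivariate score draw uses empirical-covariance matching for n > 2, so
  the latent correlation is exact and only discretization perturbs it.
- Degenerate inputs fail loudly by design: non-stationary AR coefficients,
  constant scores or constant value columns, empty atlas regions after
  masking, onsets off the TR grid or inside the discarded lead-in, singular
  designs (named columns), strata too small to split.
- All randomness is seeded; child seeds derive deterministically from the
  master seed and stay within 32-bit range. Two runs with the same config
  and seed produce bit-identical products (tested).

## 7. Known limitations

Slice-timing correction, spatial AR models beyond slice pooling, spatially
regularized mixed-effects df, Gaussian-random-field analytic cluster
p-values, TFCE, and surface-based inference are out of scope. The atlas
fixture is synthetic; real label volumes are accepted wherever an atlas is.
The Monte Carlo calibrator assumes stationary smoothness — see Section 4
for why its thresholds should be cross-checked against permutation.
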