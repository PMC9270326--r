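---
title: "Monotonic and tuned models of sub-second event timing responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monotonic and tuned models of sub-second event timing responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(timingfit)
```

## The scientific problem

Neural populations in human visual cortex respond to brief visual events —
a dot appearing and disappearing within a second. Two qualitatively
different response regimes have been described. Early visual areas respond
*monotonically*: response amplitude grows (sub-linearly) with event
duration and with event frequency. Association areas contain populations
*tuned* to a preferred event timing: their response peaks at a particular
combination of event duration and period and falls off around it. Because
fMRI integrates neural activity through the slow hemodynamic response,
distinguishing the two regimes requires forward models fit to voxel time
courses recorded while event timing sweeps gradually through the
50–1000 ms range.

`timingfit` implements that analysis end to end: stimulus schedule
construction, the two per-event forward models, hemodynamic convolution,
cross-validated fitting and voxel classification, map-level statistics, a
ground-truth model-recovery study, and a synthetic-cohort generator that
makes every stage testable without scanner data.

## Stimulus design

Events are characterized by their **duration** (onset to offset, ms) and
**period** (onset to next onset, ms); frequency is `1000/period` Hz. Four
conditions decouple duration, period and mean luminance:

* *constant luminance* — duration equals period (50–1000 ms together);
* *constant duration* — duration fixed at 50 ms, period 50–1000 ms;
* *constant period* — period fixed at 1000 ms, duration 50–1000 ms;
* *gaps* — four 10-step progressions sampling duration/period
  combinations absent elsewhere.

Each timing step nominally occupies one TR frame (2100 ms); sweeps run
ascending then descending with 16.8 s intervals of extreme timings
(duration 50 ms or 2000 ms, period 2100 ms) between them, giving blocks of
exactly 56 TRs (117.6 s) and runs of 224 TRs (470.4 s) in one of 24
condition orders.

Because event periods need not divide 2100 ms, events tile contiguously
and the repeat count of each step is chosen greedily between the two
bracketing integers so the cumulative schedule stays closest to the
nominal TR grid (ties toward fewer events; timing changes at event
onsets). Under this rule the worst cumulative onset drift is 400–500 ms
depending on condition — for repeats of a 1000 ms period against a 2100 ms
frame no contiguous tiling can stay closer than 500 ms — so
`max_drift_ms` is *reported* by `build_condition_schedule()` rather than
asserted against any particular figure. Per-TR timing labels use majority
occupancy within each TR window, with ties broken toward the later step.

## The forward models

Both models assign a relative response amplitude to each event and place
it at the event **offset**, when duration and period are fully known to
the observer. Internally all computation is in seconds and Hz; interfaces
use ms.

**Monotonic model** (4 parameters; `monotonic_params()`):

$$A(d, f) = \beta_d\, d^{\,\mathrm{exp}_d} + \beta_f\, f^{\,\mathrm{exp}_f - 1}$$

with compressive exponents $\mathrm{exp}_d, \mathrm{exp}_f \in (0, 1]$ and
non-negative component amplitudes whose ratio $\beta_d/\beta_f$ is the
reported amplitude ratio. The per-event frequency term carries the $-1$
because $f$ events per second accumulate to a per-second response
$\propto f^{\mathrm{exp}_f}$, which is non-decreasing in $f$. Pinning both
exponents to 1 recovers the linear comparison variants.

**Tuned model** (6 parameters; `tuned_params()`): an anisotropic 2D
Gaussian over (duration, period), centred on the preferred timing
$(d_p, p_p)$ with extents $\sigma_{maj} \ge \sigma_{min}$ along orthogonal
axes rotated by $\theta$, times the same compressive frequency term:

$$A(d, p) = \exp\!\left(-\tfrac12\left[\left(\tfrac{Y}{\sigma_{maj}}\right)^2 +
\left(\tfrac{X}{\sigma_{min}}\right)^2\right]\right) f^{\,\mathrm{exp}_f - 1}$$

One design decision deserves emphasis. The published coordinate transform
uses $Y = \Delta d \sin\theta - \Delta p \cos\theta$ together with
$X = \Delta d \cos\theta - \Delta p \sin\theta$; these two rows are not
orthogonal for general $\theta$, so as printed the quadratic form does not
describe an ellipse with perpendicular major/minor axes. The default
`rotation_mode = "corrected"` uses the proper rotation
($Y = \Delta d \sin\theta + \Delta p \cos\theta$), which matches the
description of an anisotropic Gaussian with major and minor axes;
`rotation_mode = "as_printed"` reproduces the literal formula for
comparison. The response is $\pi$-periodic in $\theta$, which is stored
normalized to $[0, \pi)$.

## Hemodynamics

Neural impulse trains are convolved with a difference-of-gammas HRF
(`hrf_params()`: peak gamma mean 6 s, undershoot mean 16 s, dispersions
1 s, peak:undershoot ratio 6, unit-peak normalized — the canonical
parameterization). Impulses are binned on a 10 ms grid (event durations
are multiples of 50 ms, so 10 ms bounds discretization error) and sampled
at TR onsets over a 30 s kernel support.

All predictions route through one kernel-lookup matrix
(`convolution_matrix()`): `design_matrices()` collapses it to one column
per *unique* event timing, so a model prediction is `R %*% w` for the
per-timing amplitude vector `w`. The simulator (`simulate_noiseless()`)
and the fitter share this single code path, ruling out simulator/fitter
drift, and the batched grid search evaluates thousands of candidates with
one matrix product.

Voxel time courses are per-condition averages concatenated in the
canonical order (constant luminance, constant duration, constant period,
gaps), and each 56-TR block is convolved independently: with run orders
counterbalanced across the 24 runs, cross-block spillover averages out of
the per-condition averages.

Participant-level HRF refitting (`refit_hrf()`) holds fitted neural
parameters fixed and pattern-searches the five HRF parameters to maximize
summed variance explained over voxels whose neural model explains more
than 10% of the variance, after which neural parameters are refit once
with the new HRF.

## Fitting, cross-validation, classification

**Variance explained** is the squared Pearson correlation between
prediction and data — equivalently $1 - RSS/TSS$ after refitting a free
gain and offset, which is always appropriate because fMRI amplitudes vary
arbitrarily between sessions.

**Monotonic fits** search all exponent pairs on a candidate grid; for each
pair the two component amplitudes are solved linearly with an intercept.
Negative amplitudes are disallowed (monotonically *decreasing* responses
are not part of the model): a negative component is zeroed and the other
refit alone; if that is also negative both are zero and the fit explains
nothing.

**Tuned fits** search the six-parameter grid (batched), then refine
locally from the best grid point *and* from up to two runner-up
candidates lying in other preferred-timing basins — the VE landscape
couples the preferred timings with $\theta$ and the extents, and a single
basin can trap a local search. Each refinement is a coordinate-wise
pattern search confined between the start's grid neighbors (edge
candidates extend by one grid gap) with halving steps, finished by a
bounded quasi-Newton (L-BFGS-B) polish; the result never falls below the
grid optimum. The search runs in
(pref duration, pref period, $\log\sigma_{maj}$, $\sigma_{min}/\sigma_{maj}$,
$\theta$, $\mathrm{exp}_f$) space, which keeps $\sigma_{min} \le \sigma_{maj}$
by construction. Ties in the grid are broken by first-in-grid order.

Fitted preferred timings below 60 ms or above 990 ms are flagged
**out-of-range**: such Gaussians cannot be pinned down within the
presented 50–1000 ms range and mimic monotonic responses, so their
cross-validated VE is set to 0. The candidate grid extends to 1500 ms
precisely so these optima are expressible.

**Cross-validation** fits each model on one split-half average and scores
it on the complementary one (gain and offset refit implicitly).
**Classification** (`classify_voxel()`): a voxel is *excluded* when both
models' training VE is at or below threshold (default 0.2) in both splits;
otherwise the label is the model with the higher mean cross-validated VE,
with the tuned model eligible only when not out-of-range, and ties going
to the more parsimonious monotonic model.

**Grids** (`grid_spec()`) are configurable; none are prescribed by the
analysis being reimplemented, so recovery behavior rather than grid
identity is the contract. The `"default"` density uses exponent steps of
0.05 and preferred timings every 100 ms (25–1500 ms span); the `"coarse"`
density (exponent step 0.1, preferred timings every 200 ms, leaning on the
pattern search for refinement) is what the large simulation studies and
the worked examples use — on one CPU it fits a voxel in well under a
second while still recovering noiseless preferred timings to well within
50 ms.

## Map-level statistics

`map_median_ve()` takes per map × hemisphere × split medians of each
model's cross-validated VE over voxels passing the training-VE threshold
(cells with no passing voxel are absent, and exclusion is applied per
split). `compare_models_by_map()` then runs paired two-sided Wilcoxon
signed-rank tests (hemisphere × split × participant measurements as
pairs), BH-FDR across maps, effect sizes $r = Z/\sqrt{n}$, and bootstrap
CIs of each median. Wilcoxon p values use the exact signed-rank null
distribution for tie-free $n \le 25$ and the tie/continuity-corrected
normal approximation beyond — the convention of the originating
workflow's `signrank`; the normal approximation alone deviates from the
exact two-sided p by up to ~0.04 at small n. Zero differences are dropped
(classical convention). Bayes factors are out of scope; tables carry an
`NA` placeholder column so layouts match.

`anova_nfactor()` fits fixed-effects ANOVAs (participant treated as a
fixed factor, matching `anovan` defaults) with Type III sums of squares on
sum-to-zero contrasts and reports partial $\eta^2$. Parameter comparisons
across maps use `dunn_holm_sidak()` (rank-based Dunn z with tie
correction; step-down Šidák adjustment) gated by `jarque_bera()`
normality. These three are implemented in-package because no installed
package exposes the required Z/adjusted-p surface; each is verified
against hand computations and enumeration oracles in the test suite.

Eccentricity analyses: `eccentricity_bins()` pools voxels across
hemispheres and splits into half-open 0.2° bins centred 0.1–5.5°,
dropping bins under 50 measurements and voxels with no variance explained
by either model. `fit_eccentricity_progression()` fits a
cumulative-Gaussian sigmoid (inflection, slope, maximum, minimum; CI by
bin bootstrap, 10,000 iterations by default) and a quadratic (analytic
CI), choosing the curve best correlated with the bin means — ties go to
the quadratic, which nests the linear case. `near_far_compare()` contrasts
mean VE below 1° against 2–5.6°, with the three-factor ANOVA
(participant, map, range; map × range interaction) and per-map Wilcoxon
tests with FDR, for the monotonic VE, the tuned VE, and their difference.

## Model recovery and the synthetic cohort

`run_recovery()` re-creates the validation study: ground-truth parameters
drawn from broad uniforms (exponents U(0.05, 1); preferred timings
U(50, 1200) ms with duration below period; $\sigma_{maj}$ U(100, 1500) ms;
$\theta$ U(0, $\pi$)), signals z-normalized and degraded with independent
Gaussian noise at SDs 0–6 in steps of 0.5 (SNR 1/6 to infinite), two
realizations per voxel, then the full fit/cross-validate/classify
pipeline. Outputs are stratified by true kind, noise SD, training-VE bin
and whether the *estimated* preference is inside the presented range —
out-of-range estimates are not taken as evidence of tuning. The affine
output scaling (`amplitude_mean = 100`, `amplitude_sd = 2`, stand-ins for
the unpublished observed-data statistics) provably cancels in the
correlation-based VE, and a test asserts that invariance.

`generate_cohort()` builds a cohort of participants × hemispheres × maps
(default: 8 participants, 2 hemispheres, ten maps V1 → iPCS) in which the
tuned-voxel fraction rises logistically along the hierarchy rank between
0.1 and 0.9. Eccentricities are sampled from a truncated exponential on
[0, 5.6°] (scale 2°, mimicking foveally-magnified sampling). Because
`degrade()` z-normalizes every signal, eccentricity-dependent *signal
strength* is implemented through SNR: a monotonic voxel's noise SD is
multiplied by $e^{ecc/1.5°}$ (capped at SD 6), while tuned voxels' SNR is
eccentricity-independent. Per-voxel base noise SDs are drawn from
U(0.4, 1.6) so that VE distributions straddle the 0.2 threshold and the
exclusion logic is genuinely exercised. Cohorts are bit-reproducible from
the master seed, and the ground-truth table suffices to reconstruct every
noiseless signal through the shared forward path.

What passing tests on this cohort do and do not show: the generator
reproduces the *statistical structure* the analysis assumes — mixtures of
the two response kinds, a hierarchy gradient, eccentricity-dependent
monotonic SNR, split-half noise independence — not the spatial
correlations, physiological noise spectra, HRF variability or partial
volume effects of real recordings. End-to-end tests therefore validate
the pipeline's ability to recover engineered effects, not any claim about
cortex.

## Problem sizes and numerical choices

The shipped test and acceptance runs use desk-scale sizes chosen to make
the statistical checks decisive while keeping a full run comfortable on a
single CPU: 200 noiseless voxels per model for parameter recovery, 8
voxels per kind per noise level across the 13-level noise grid for
classification rates, and a 2-participant × 2-hemisphere × 10-map × 16-voxel
cohort (640 voxels) for the end-to-end hierarchy and eccentricity checks,
all on the coarse grid with the pattern-search refinement. Key numerical
conventions: times are integer ms internally until the forward models
convert to seconds; VE comparisons use squared correlation throughout;
the pattern search stops when VE gains fall below $10^{-4}$ or steps
shrink below 1/128 of the neighbor span; degenerate inputs (constant data
or predictions) score VE 0 rather than erroring mid-pipeline.

## Limitations

* The exact stimulus-scheduling rule, candidate grids, descent settings
  and HRF parameterization of the original analysis are not published;
  this package states its own choices above and exposes them as
  configuration.
* Map-level real-data results (published medians, Z and F values) are
  computed on restricted-access recordings and are not reproduction
  targets here; the engineered-effect suites are the testable surface.
* Bayesian paired comparisons are not implemented (placeholder column
  only); surface-based clustering that defines timing-map ROIs is
  consumed as annotations, not computed.
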