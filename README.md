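# timingfit

Voxelwise modelling of fMRI responses to sub-second visual event timing:
does a voxel respond **monotonically** to event duration and frequency, or
is it **tuned** to a preferred event timing?

Early visual cortex responds more the longer and the more often a brief
stimulus appears; higher association areas contain populations tuned to a
particular combination of event duration and period. `timingfit`
implements the forward-modelling analysis that separates the two on fMRI
time courses, exercised entirely on synthetic data:

* **Stimulus design** — the four event-timing conditions (constant
  luminance / duration / period, and gaps), tiled onto a 2100 ms TR grid:
  56-TR condition blocks, 224-TR (470.4 s) runs, 24 condition orders.
* **Forward models** — per-event response amplitude at the event offset:

  monotonic (4 free parameters)

      A = beta_dur * Duration^expDur + beta_freq * Frequency^(expFreq - 1)

  tuned (6 free parameters): an anisotropic 2D Gaussian over
  (duration, period), centred on the preferred timing with extents
  sigma_maj >= sigma_min along axes rotated by theta, times the same
  compressive frequency term.
* **Hemodynamics** — two-gamma HRF convolution on a 10 ms grid sampled at
  TR onsets, with participant-level HRF refitting; simulator and fitter
  share one prediction code path.
* **Fitting** — batched grid search plus coordinate-wise pattern-search
  refinement; non-negative component amplitudes with the stated fallback;
  split-half cross-validation with gain/offset refit; tuned fits whose
  preferred timing falls outside 60–990 ms score zero cross-validated
  variance explained; voxels classified monotonic / tuned / excluded at a
  0.2 training-VE threshold.
* **Statistics** — map-level median VE, Wilcoxon signed-rank (exact for
  small n) with BH-FDR and effect size r = Z/sqrt(n), bootstrap median
  CIs, fixed-effects n-factor ANOVA (Type III), Dunn's test with
  Holm-Šidák correction, Jarque–Bera gate, eccentricity binning with
  sigmoid/quadratic progression fits, and near/far eccentricity
  comparisons.
* **Validation** — a ground-truth model-recovery study across noise SDs
  0–6, and a seeded synthetic-cohort generator with a rising tuned
  fraction along the visual hierarchy and eccentricity-dependent
  monotonic SNR.

## Worked example

```r
library(timingfit)

dm  <- design_matrices(timing_design())          # 224 TRs, 74 unique timings
p   <- tuned_params(pref_duration_ms = 400, pref_period_ms = 700,
                    sigma_major_ms = 300, sigma_minor_ms = 150,
                    theta_rad = 0.5, exp_freq = 0.4)
pair <- degrade(simulate_noiseless(p, dm), noise_sd = 1, seed = 5)
fit  <- fit_voxel(pair$a, pair$b, dm, grid_spec("coarse"))

fit$classification
#> [1] "tuned"
round(c(fit$mono$ve_cv, fit$tuned$ve_cv), 3)
#> [1] 0.059 0.051 0.490 0.478
round(unlist(fit$tuned$a$params)[1:2], 1)
#> pref_duration_ms   pref_period_ms
#>            387.5            687.5
```

A tuned voxel simulated at SNR 1 is classified tuned: the tuned model
cross-validates at VE ≈ 0.49 on the held-out split against ≈ 0.05 for the
monotonic model, and the preferred timing is recovered to within ~15 ms of
the generating (400, 700) ms. A monotonic voxel run through the same
pipeline is caught the other way — the tuned fit drifts out of range, its
cross-validated VE is zeroed, and the voxel is labelled monotonic.

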