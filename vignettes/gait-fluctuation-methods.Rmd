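---
title: "Fluctuation indices of whole-body gait dynamics: model, estimator and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fluctuation indices of whole-body gait dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitfluct)
```

## The scientific problem

Healthy human movement is variable, but not randomly so: stride-to-stride and
posture series typically show long-range correlations whose power spectral
density (PSD) falls off as a power law, the "1/f" or pink-noise signature. In
several movement disorders this structure degrades towards uncorrelated
(white) variability. gaitfluct quantifies that structure for the *whole body*
from markerless motion capture: a smartphone pose tracker streams 27 body
keypoints at 30 fps while the subject walks in a 1 m circle, and for each of
the 26 keypoints other than the navel we reduce the per-frame Euclidean
distance to the navel to one number per trial, the **fluctuation index**

$$\log_{10} P(f) = \alpha \, \log_{10} f + \log_{10} k,$$

the OLS slope $\alpha$ of log PSD on log frequency. $\alpha \approx 0$ means
white noise, $\alpha \approx -1$ pink noise, $\alpha \approx -2$ Brownian
noise. In the clinical cohorts this package models, patients with idiopathic
normal pressure hydrocephalus (iNPH) and Parkinson's disease (PD) show
systematically smaller $|\alpha|$ than controls at every body position, with
iNPH below PD.

## The estimator, step by step

1. **Distances** (`navel_distances`): per-frame 3D Euclidean distance from
   the navel to each of the 26 target keypoints. Using relative distances
   removes the tracker's arbitrary origin; the statistic is invariant to
   whole-body translation and, up to the intercept, to global rescaling.
2. **Window** (`extract_window`): one contiguous 128-frame (~4.27 s) slice.
   The default `stable` strategy discards 30 frames at each end (start-up and
   stopping transients) and picks the admissible window minimizing the
   variance of first differences, ties going to the earliest start so the
   choice is deterministic. 128 is canonical — a power of two; other even
   lengths are accepted but flagged.
3. **Periodogram** (`psd_periodogram`): subtract the window mean (no further
   detrending, no taper, no Welch averaging — the statistic is defined on one
   raw transform of one window), FFT, one-sided PSD
   $P_i = \tfrac{2}{n f_s}|X_i|^2$ at $f_i = i f_s / n$ for
   $i = 1, \dots, n/2-1$. DC and Nyquist are excluded: DC is identically zero
   after mean removal and both would otherwise distort a log–log fit. At
   $n = 128$, $f_s = 30$ Hz this gives 63 ordinates from 0.234 to 14.766 Hz.
4. **Fit** (`fit_loglog`): OLS of $\log_{10} P$ on $\log_{10} f$ over all
   bins. The fitted band is a knob (`f_min`, `f_max`) for sensitivity
   analysis, but the default uses every positive non-Nyquist bin; whether the
   original clinical analysis restricted the band, tapered, or used natural
   logs is not documented, and none of those choices moves the slope (log
   base) or is adopted here (band, taper). Zero-power bins cannot enter a log
   fit; they are dropped and counted (`n_dropped`), and fewer than three
   positive bins is a degeneracy error rather than a number.

`fluct_fit()` composes these per keypoint and returns a classed fit with
`coef`, `summary`, `residuals` and `plot` methods; `fluct_cohort()` lifts it
to a labelled collection of trials.

## The synthetic cohort: what it emulates and what it does not

No per-trial clinical recordings are public — only group-level summary means —
so the package ships a generator whose outputs exercise every downstream
stage under the study's recording conditions: 30 Hz, 128-frame eligibility,
27 keypoints, circular walking geometry.

`powerlaw_series()` synthesizes noise spectrally. In
**deterministic-amplitude** mode the Fourier amplitudes are fixed so that the
raw periodogram equals $\text{scale} \cdot f^\alpha$ *exactly* at every
fitted frequency (phases random); the estimator must then return $\alpha$ to
machine precision for any seed, which turns correctness of the whole
distance→window→periodogram→fit chain into a sharp test. In **stochastic**
mode the coefficients are independent complex Gaussians with variance
$\propto f^\alpha$, giving the exponential periodogram scatter of real
colored noise; the log-periodogram then has a frequency-independent offset,
so the slope estimate stays unbiased while acquiring realistic variance
(about 0.18 SD per 128-sample series).

`simulate_trial()` places the navel on a 1-unit-diameter circle (one lap per
trial) and each keypoint at `navel + u * (d0 + g(t) + s(t))` along its fixed
skeleton direction `u`: `d0` is a plausible but arbitrary unitless offset
magnitude (head 0.55, ankle 0.90, ...; only the positivity margin matters),
`g` an optional cadence sinusoid and `s` the power-law series rescaled to
`noise_rms` (default 0.01, well inside the `d0/2` positivity margin —
exceeding it is an error, not a silent clip). The navel-distance series is
therefore *exactly* `d0 + g + s`, so generation targets propagate to the
estimator without approximation. The cadence amplitude defaults to 0 because
a spectral line at the step frequency biases the slope fit; it exists for
realism demonstrations, not validation runs.

`simulate_cohort()` defaults to the study conditions: 117/56/184 trials over
23/23/92 subjects for iNPH/PD/control, per-group target exponents taken from
the packaged table of published group means, 128 frames at 30 fps. The
published table reports no dispersions, so the between-trial SD is a free
simulation parameter (default 0.15) and no claim is made that simulated
p-values reproduce the published ones. The SD is realized as **one** Gaussian
offset per trial shared across keypoints — "between-trial" variation, a trial
being globally better or worse, which matches the day-to-day symptom
fluctuation that motivated repeated trials; per-keypoint independent draws
would be a different (between-keypoint) variance component. Trials are
treated as exchangeable units, as in the published ANOVA; the generator does
not model within-subject correlation, limb kinematics, joint constraints or
camera noise. Passing tests therefore certify the *estimator and statistics
machinery*, not the biomechanical realism of the inputs.

## Cohort statistics

Per keypoint, group means are compared by classical one-way fixed-effects
ANOVA and Tukey HSD pairwise comparisons (studentized range on the pooled
within-group variance with Tukey–Kramer standard errors for unbalanced
groups). These are implemented in closed form so degenerate inputs are
defined rather than accidental:

* all observations identical → $F = 0$, $p = 1$, all pairwise $p = 1$;
* zero within-group variance with unequal means → $F = \infty$, $p = 0$;
* samples identical to working precision (relative range $\le 10^{-10}$) are
  treated as identical — without this guard, a dispersion-free synthetic
  cohort recovered to $10^{-14}$ would hand the ANOVA pure rounding noise and
  produce arbitrary p-values.

`stats::aov` and `stats::TukeyHSD` serve as independent oracles in the test
suite. The iNPH-vs-PD contrast is flagged at the 5% level, as published. No
multiple-testing correction across the 26 keypoints is applied by default
(fidelity to the published analysis); `p_adjust = "holm"` is the escape
hatch. Likewise the unit of analysis is the trial, replicating the published
design despite its pseudo-replication (117 iNPH trials come from 23
patients); `unit = "subject"` averages within subject first. The cohort table
orders rows in upper/lower × trunk/limb blocks by ascending absolute control
mean, the published layout, and `ordering_count()` reports in how many of
the 26 positions the strict magnitude ordering |iNPH| < |PD| < |control|
holds (26 of 26 in the published means).

## Numerical choices and edge cases

* Windows must be even-length ≥ 8 (the spectral synthesis and one-sided PSD
  both assume it); 128 is canonical.
* Constant windows have no spectrum: degeneracy error.
* Trials with missing samples are rejected at load by default; dropout gaps
  of ≤ 3 frames per coordinate can be linearly interpolated on request
  (`repair = "interpolate"`). Longer gaps are irreparable for an FFT-based
  statistic.
* Seeded generators save and restore the caller's RNG state, so library code
  never perturbs a user's stream.
* Stable-window ties break to the earliest start; all orderings and hashes
  avoid timestamps, so every pipeline artifact is byte-reproducible from
  (config, seed).

## Problem sizes used in the shipped checks

The validation suite runs, among others: exact recovery on the 13-point
exponent grid $\{0, -0.25, \dots, -3\}$; 300-replicate stochastic
unbiasedness at $\alpha \in \{0, -1, -2\}$ plus white-noise and
integrated-noise (Brownian) limits at $n = 128$, where the finite-size slope
of an integrated white series lands near $-1.8$; a dispersion-free 9-trial
cohort recovered to $10^{-6}$; and a full-size cohort (117/56/184, SD 0.15)
whose group means return to the published targets within ±0.05 with the
magnitude ordering reproduced in ≥ 24/26 positions. These sizes were chosen
as the smallest that make each property sharp.

## Known limitations

* The on-disk trial format is this package's own; the pose tracker's native
  export schema is not public, so adapters are left to the user.
* The periodogram-slope estimator is the defined statistic; DFA, wavelet or
  multifractal estimators are out of scope by design.
* With 63 bins of a single raw periodogram the per-trial index carries ~0.18
  SD of estimator noise; group inference relies on trial counts, and single
  trials should be read accordingly.
* The generator's skeleton is a static template — adequate for spectral
  validation, not for kinematic plausibility.
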