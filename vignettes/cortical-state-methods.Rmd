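---
title: "Cortical state estimation from intracranial field potentials: models and methods"
author: "corstate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cortical state estimation from intracranial field potentials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corstate)
```

## The scientific problem

Ongoing cortical population activity drifts between a *synchronized* regime
(large, slow, coordinated fluctuations) and a *desynchronized* regime (small,
fast, irregular activity), even at constant vigilance. In intracranial field
potential (IFP/ECoG) recordings this continuum is summarized per trial by the
**power ratio**

$$ \mathrm{PR} = \frac{\overline{x_{\mathrm{low}}^2}}{\overline{x_{\mathrm{high}}^2}}, $$

the mean voltage-squared power of the zero-phase band-passed signal in the
low band (2.5--12 Hz) divided by that in the high band (12--80 Hz), computed
over the 400 ms of ongoing activity preceding the first stimulus of a trial.
High PR marks the synchronized state. The package implements the full
analysis chain around this statistic: preprocessing (common-average
referencing, line-noise removal, amplitude-threshold rejection of
epileptiform trials), state labelling by median split, the probability that
an electrode shares its state with the rest of the array, state-conditioned
behavioral contrasts for detection and discrimination tasks, evoked-response
coupling, and a cross-validated Fisher linear discriminant decoding trial
outcome from the pre-stimulus state.

Because clinical ECoG recordings cannot be redistributed, the package also
contains a first-class synthetic session generator with a controllable
latent state. Every downstream stage is validated against that ground truth.

## Filtering

All band isolation uses Chebyshev Type II designs applied forward-backward
(zero phase), mirroring standard practice for pre-stimulus power estimates
where phase distortion would smear activity across the stimulus boundary.

* **Cutoffs.** The stopband edges sit 0.3 Hz outside the nominal band
  (2.2 and 12.3 Hz for the low band; 11.7 and 80.3 Hz for the high band;
  60 ± 0.6 Hz for the line-noise notch), with 60 dB stopband attenuation per
  pass. The forward-backward application doubles the attenuation in effect
  and nullifies the phase.
* **Order.** Only edges and attenuation are fixed by the analysis
  definition; the order is chosen as the minimal Chebyshev II order whose
  passband edges -- one transition width inside the stopband edges -- see at
  most 0.5 dB. The transition width per edge is `max(0.6 Hz, 5% of the edge
  frequency)`: 0.6 Hz at 2.5 and 12 Hz, where the bands must separate
  sharply, and 4 Hz at 80 Hz, where a 0.6 Hz transition would inflate the
  order several-fold (to roughly 120 poles) without changing any quantity
  the pipeline measures. This yields prototype orders 23 (low band), 24
  (high band) and 7 (notch).
* **Numerics.** The designs are carried in zero-pole-gain form through the
  analog prototype, band transform and bilinear transform, and realized as
  second-order sections; transfer-function coefficients are numerically
  singular at these narrow relative bandwidths. Filtering runs in compiled
  code with odd-reflection padding (0.3 s by default) and steady-state
  initial conditions, and matches a reference double-precision
  implementation of the same second-order-section algorithm to ~1e-8.
* **Edge effects.** The sharpest poles lie within 2e-4 of the unit circle
  and ring for seconds. The pre-stimulus analysis window is therefore kept
  interior to the epoch (400 ms of pre-cue data precede it by default), and
  tests that probe stopband floors use long signals and deep-interior
  windows. On epoch-length data the 60 Hz notch is transient-limited to
  roughly 15 dB of suppression; continuous recordings should be notched
  before epoching when possible.

## The synthetic session generator

`simulateSession()` emulates the statistical structure the analyses assume,
not the biophysics of ECoG. Per trial $t$ and electrode $i$:

* **Latent state.** $\log \mathrm{PR}_{ti} = \mu + \sigma(\sqrt{s}\, g_t +
  \sqrt{1-s}\,\varepsilon_{ti})$ with a global latent $g_t$ and private
  deviations, so a fraction $s$ (`stateSharing`) of log-PR variance is
  shared across the array. Defaults: $\sigma = 0.5$ (the log-scale spread is
  not published for the reference data; this value gives trial-to-trial PR
  factors of ~2.7 at ±2 SD, a realistic range), and
  $\mu = \log(10.62) - \sigma^2/2$ so that the mean PR is 10.62.
  `stateSharing = 0.13` follows from the closed form for median-split
  agreement of bivariate normals, $P = 1/2 + \arcsin(\rho)/\pi$ with $\rho =
  s/\sqrt{s + (1-s)/n_E}$: at 50 electrodes it puts the same-state
  probability at 0.61.
* **Trace synthesis.** Each trace is the sum of two band-limited Gaussian
  noise components, shaped in the frequency domain by the squared magnitude
  response of the very band-pass filters the analysis applies -- generator
  and analysis agree on the band definitions by construction -- and scaled
  so the realized pre-stimulus-window band powers express the trial's
  latent PR exactly (the scaling also pre-compensates the small spectral
  shrinkage the analysis filter re-application causes). Synchronization
  *redistributes* power: the low band gains what the high band loses, with
  the total band power constant (1100 uV^2) in expectation. This matches
  the phenomenology of the synchronized state (low-frequency power up,
  high-frequency power down) and keeps trial amplitudes homogeneous, so the
  amplitude-threshold rejection rule stays specific to genuine bursts. The
  measured mean PR runs ~5% below the latent mean because the analysis
  filters shave the band edges of an already band-limited process; the
  latent distribution itself is exact.
* **Behavior.** $P(\mathrm{correct}) = \mathrm{logit}^{-1}(a_\tau + b_\tau
  z_t)$ where $z_t$ standardizes the population-mean latent state, $a_\tau$
  encodes the task's baseline rate (64.38% detection, 55.83%
  discrimination) and $b_\tau$ is `+0.6` for detection and `-0.6` for
  discrimination. These couplings reproduce a low/high-state performance
  split of roughly 53% vs 74% (detection; reversed for discrimination).
  Under a single shared latent they produce electrode-level PR percent
  differences of about ±10--15%, smaller than reported in patient data
  (±21--25%); matching both the performance split and the electrode-level
  contrast with one coupling is not possible in this one-factor model, and
  the sign pattern is what the validation grades. Reaction times follow
  $\mathrm{RT} = 600 - 40\,\mathrm{sign}(b_\tau) z_t + \mathcal{N}(0,
  150^2)$ ms, giving the negative state--RT correlation for detection and
  positive for discrimination.
* **Evoked responses.** Stimulus windows receive additive broad-band
  transients with log-power $\log 600 + 0.45\, z_{ti} + \mathcal{N}(0,
  0.55^2)$ (per-electrode state $z_{ti}$). With the state-dependent
  background this calibrates the per-electrode Pearson correlation between
  log PR and evoked power (dB) to ~0.30. For discrimination trials the test
  transient differs from the target by $0.08 + 0.42(-z_t)$ dB plus noise;
  measured through the full pipeline (where the ongoing background dilutes
  the transient contrast) the low/high-state group means land near +0.2 and
  -0.1 dB. The transient is kept modest (SNR ~0.5 against the ongoing
  activity) deliberately: much larger transients trip the epileptiform
  rejection rule on their own.
* **Artifacts.** With probability `artifactRate` (default 0.05) a trial
  receives a 3 Hz alternating square-wave burst on every electrode, 8 trace
  SDs in amplitude and 10% of the epoch long -- comfortably beyond the
  rejection rule's 3 SD / 5% thresholds. Epileptiform discharges are
  spatially widespread, hence the every-electrode convention; it also gives
  the rejection stage an unambiguous ground truth.
* **Determinism.** All draws flow from the single `seed` in the
  configuration; identical configurations give bit-identical sessions, and
  the caller's RNG stream is left untouched.

Trials are generated independently (the reference analyses find no trial-lag
autocorrelation in the state), the auditory cue evokes no response, and no
1/f background outside the two analysis bands is modelled. Passing tests
therefore certify the pipeline's correctness and calibration under the
stated statistical structure -- not robustness to non-stationarity, shared
noise sources, or volume conduction in real recordings.

## Epileptiform rejection

For each task and electrode, the threshold is `TH = mean + 3 sd` of the
absolute raw signal over all of that task's trials concatenated; a trial is
rejected when `|x| > TH` (strictly, so a constant signal rejects nothing)
for at least 5% of its samples, and an electrode is excluded when fewer than
50 clean trials survive in either task. Two properties of this rule matter
in practice:

* its false-positive rate is irreducibly a few percent per electrode (the
  supra-threshold fraction of correlated signals is heavy-tailed), so
  `cleanSession()` drops a trial only when **more than half** of the
  retained electrodes reject it -- genuine discharges are widespread, while
  isolated crossings are ordinary amplitude fluctuations. The per-electrode
  rejection matrix remains available for analyses that keep per-electrode
  trial sets.
* at high contamination the threshold inflates with the artifacts
  themselves: with bursts on every trial covering fraction $\rho$ of the
  epoch, the variance term alone contributes $3\sqrt{\rho}$ burst
  amplitudes to TH, so bursts at 10% duty are only marginally detectable
  regardless of their size. Validation fixtures use shorter or larger
  bursts accordingly.

## Spectral estimation

Per-trial spectra are multitaper estimates (discrete prolate spheroidal
tapers from the tridiagonal eigenproblem), time-bandwidth product 3 with 5
tapers for the 400 ms window; spectrograms use 200 ms windows stepped by
50 ms. These are conventional settings for short ECoG windows and are
exposed as arguments. The z-scoring across trials at each grid point forces
the all-trial mean to zero, which implies the exact identity
$\sum_c n_c \bar z_c(f) = 0$ over conditions -- a machine-precision
invariant the tests assert. Zero-variance grid points return z = 0 with a
degeneracy flag rather than NaN. The PR itself is computed in the time
domain (mean squared band-passed voltage), never by spectral integration;
FFT band-power integration serves only as an independent oracle in the
tests.

## Decoding

`decodeOutcome()` draws equal numbers of correct and incorrect trials
without replacement, runs a stratified 5-fold cross-validated Fisher LDA
(scatter-ratio direction, midpoint threshold, ridge `1e-3 * trace/dim` only
when the within-class scatter is ill-conditioned), and repeats; the p-value
is the fraction of iterations below the 0.5 chance level. Two empirical
properties shaped the defaults:

* **Feature choice.** The default feature is the across-electrode mean log
  PR -- the trial's cortical state. The per-electrode vector mode
  (available via `mode = "vector"`) overfits badly at tens of electrodes
  and of the order of a hundred trials: cross-validated classifiers under
  balanced resampling of a finite pool have a known negative bias (the test
  folds are anti-correlated with the training folds), measured here at
  0.45--0.47 null accuracy for 30--50 features, which also buries the
  population-level signal.
* **Dataset noise at the null.** Even with one feature, the finite trial
  pool has a chance feature--outcome correlation that every balanced
  subsample inherits, so the accuracy distribution of a single session
  concentrates near a dataset-specific value (SD ~0.025 across sessions at
  200 trials). Chance-level calibration is therefore assessed across
  independent sessions, not within one.

## Statistical conventions

Wilcoxon signed-rank and rank-sum tests carry explicit sidedness; exact
nulls are used for small samples without ties (below n = 25 one-sample, at
or below 10 per group two-sample), the normal approximation with continuity
correction otherwise. All PR hypothesis tests run on log PR (the trial
distribution is log-normal); percent-difference effect sizes use raw PR,
with the incorrect-trial mean as denominator. Bootstrap p-values are
smoothed as $(k+1)/(B+1)$ so complete separation reports the attainable
floor instead of zero; for binary outcomes the within-group resampling is
drawn in closed form from binomial distributions, making 10^6 iterations
cheap. Bonferroni correction is plain `min(1, p * m)`. The tertile variant
of the performance analysis uses equal-width bins over the range of the
population state (equal-count binning is available through the median-split
path); the quartile comparison of same-state probabilities uses the
unpaired rank-sum test, as the first- and fourth-quartile electrode groups
are disjoint.

## Problem sizes used in validation

The bundled checks simulate at the study's own scale where the property
demands it -- 50 electrodes x 120 trials per task for the sign-pattern
replication (100 seeded replicates), 10 x 200-trial zero-coupling sessions
for the decoder's chance level, 10,000 permutations for the same-state
shuffle null, 10,000 null simulations at n = 97 for the signed-rank type-I
rate -- and at reduced sampling rates (500 Hz) or array sizes elsewhere,
where the property under test does not depend on them.

## Known limitations

* The generator's single global latent cannot reproduce electrode-level
  contrast magnitudes and population-level performance splits
  simultaneously (see above); only signs and calibrated magnitudes of the
  targeted quantities should be compared.
* Epoch-level filtering limits the notch and the 2.5 Hz band edge: the
  sharpest poles ring longer than an epoch, so absolute stopband floors are
  only reached on long continuous data.
* The rejection rule's threshold is contaminated by the artifacts it hunts
  at high artifact rates; it behaves as intended for occasional discharges.
* Session serialization is RDS plus a CSV behavioral table; no hierarchical
  array-container backend is provided.
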