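---
title: "Directed connectivity from oscillatory recordings: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Directed connectivity from oscillatory recordings: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dirflow)
```

## Overview

`dirflow` implements a complete analysis chain for directed (effective)
connectivity in epoched multichannel oscillatory recordings such as
resting-state EEG or MEG:

1. **Spectral preprocessing** — average reference, epoch-averaged tapered
   power spectra, canonical and IAF-individualized frequency bands, band
   power.
2. **Source reconstruction** — frequency-domain (DICS-style) beamformer:
   band-averaged cross-spectral density (CSD), unit-gain spatial filters,
   voxel power maps, surrogate-flagged peaks, pooled regional source
   signals.
3. **Stationary directed connectivity** — multivariate autoregressive
   (MVAR) modelling with AIC order selection, partial directed coherence
   (PDC) and renormalized PDC (RPDC), spectral coherence.
4. **Time-resolved directed connectivity** — time-varying VAR coefficients
   via dual extended Kalman filtering (DEKF) and PDC evaluated at each time
   point (tPDC), with per-connection temporal-variability summaries.
5. **Edge validation** — window-shuffling bootstrap surrogate thresholds
   and the time-reversal test (TRT), with uni-/bidirectional pair labels.
6. **Evaluation** — 20-dimensional per-subject feature vectors (4 measures
   x 5 bands), group statistics, and polynomial-kernel SVM classification.

A synthetic-cohort generator with ground-truth directed networks provides
the test bed: everything the test suite asserts is computed on data whose
directed structure is known by construction.

## The synthetic cohort

### Ground-truth networks

`make_group_network()` builds two templates around a designated "thalamic"
node (the last source) and "cortical" nodes (the rest):

* **control-like** — reciprocal lag-1 coupling between every cortical node
  and the thalamic node (bidirectional edges), constant in time;
* **patient-like** — only the cortex-to-thalamus direction, at half the
  coupling strength, with a slow multiplicative modulation of the coupling
  coefficient (`coupling * (1 + 0.2 s(t))`, `s` a smoothed standard-normal
  random walk). The modulation gives this group the larger temporal
  variability of directed strength that the time-resolved analysis is
  designed to detect.

Each source is an AR(2) resonator. Two design choices matter here:

* **Pole radius from band width.** The AR(2) resonance half-width is about
  `fs (1 - r) / pi` Hz. A fixed radius would give slow narrow bands (delta,
  theta) resonances far wider than the band itself, so the radius is chosen
  per band to keep the half-width at 40% of the band width, floored at
  0.95. With this rule every band-assigned source keeps well over 60% of
  its power inside its band at the default sampling rate of 256 Hz.
* **Pole frequencies spread within the band.** Same-band sources are
  placed at distinct frequencies across the middle half of the band.
  Identical-frequency resonators injection-lock through even weak
  reciprocal coupling (pilot runs showed inter-source correlations of
  0.6-0.8), and a minimum-variance beamformer partially cancels correlated
  sources — the classic correlated-dipole limitation of DICS-type filters.
  Spreading the frequencies keeps same-band sources spectrally distinct
  while remaining inside the band.

Stability is enforced by checking the companion-matrix spectral radius and,
when coupling insertion destabilizes the system, scaling the cross-coupling
down by 0.9 at most 20 times (with a warning). This contract has a real
consequence: reciprocal coupling between slow, narrow-band resonators
(delta, theta) sits outside the stabilizable region entirely — the
stationarity margin for the lag-1 coefficient of a low-frequency resonator
is a few thousandths — so a bidirectional delta template raises an explicit
error rather than silently producing an unstable system. Fast bands
(alpha and up) accommodate reciprocal coupling after rescaling.

### Sensor projection

`make_cohort()` jitters each subject's coupling coefficients
(multiplicative Gaussian, `jitter_sd` default 0.05 — a plausible
between-subject spread; no empirical value exists for it), places sources
at random distinct voxels of a synthetic lead field, projects to sensors,
adds 50/50 white-plus-pink noise at the requested SNR, and optionally
applies instantaneous cross-channel mixing `(1 - leakage) I + leakage M`
(`M` symmetric stochastic) as a volume-conduction stand-in. The mixing is
zero-lag by construction, which is exactly what the time-reversal test is
supposed to reject.

The synthetic lead field is a random Gaussian gain matrix with
average-referenced, unit-norm, separability-checked columns on a regular
5-mm grid. Columns are average-referenced because the sensor data are
analyzed in the average reference; a lead field expressed in a different
reference systematically degrades beamformer localization. What the
generator does **not** emulate: dipole physics and realistic head
geometry, artifacts (ocular, muscle), non-stationary background rhythms,
and realistic inter-subject anatomical variability. Passing tests
therefore show that the estimators recover the structure they are defined
on — not that they are robust to everything real recordings contain.

## Spectral analysis

Epochs are demeaned, multiplied by a 10% cosine-tapered (Tukey) window,
and zero-padded to the requested frequency resolution (0.25 Hz by default;
1-s epochs natively support only 1 Hz, so the padding factor is 4). Power
is a one-sided PSD, epoch-averaged. Band power is the mean over the bins
inside the closed interval `[lo, hi]` — the integrated area divided by the
width in points.

The individual alpha frequency (IAF) is the frequency of maximal
channel-mean power in 8-13 Hz; a strict local maximum is required, with a
flagged fallback to the in-range global maximum (flat or monotone spectra
give no meaningful peak), and ties break toward the lower frequency.
Band individualization rescales every canonical edge `e` to
`(0.1 e) * IAF`, the identity at IAF 10 Hz: an IAF of 10.1 Hz maps the
delta band (1-3 Hz) to 1.01-3.03 Hz. The individualized gamma upper edge
is capped at the canonical 49 Hz and, when a sampling rate is supplied, at
`fs/2 - resolution`.

## Beamformer source analysis

The band CSD is the epoch- and bin-averaged matrix of tapered Fourier
cross-products, Hermitized by averaging with its conjugate transpose. The
spatial filter per voxel is the unit-gain minimum-variance solution
`w = (l' C^-1 l)^-1 l' C^-1` with `C = Re(CSD)` regularized by
`reg_lambda` (default 0.05, i.e. 5% of the mean CSD diagonal — the
regularization has no reported value anywhere, so a standard beamformer
default is used). Voxel power is `Re(w S w^H)`; peaks are 26-neighbourhood
local maxima.

Peak significance uses within-subject permutation surrogates: the epoch
order is shuffled independently per channel, which preserves each
channel's marginal spectrum while destroying cross-channel alignment, and
the observed voxel power is compared with the 99th percentile of that
voxel's surrogate distribution. Two calibration facts are worth knowing:

* With `n_perm` surrogates and an estimated percentile the null exceedance
  rate is close to `2/(n_perm + 1)` (about 2% at 100 permutations), not
  exactly 1% — the usual order-statistic effect.
* The calibration holds for independent channels. Average-referencing
  itself introduces common-mode cross-channel correlation which the
  shuffling removes, so on re-referenced pure-noise data the empirical
  rate is somewhat higher than the design rate.

Pooled regional signals: the region is the flagged peak plus its
26-neighbourhood (an explicit, configurable choice — only "region" is
specified anywhere). The region's voxel series are combined through their
*band-limited* second-order statistics: the sensor CSD is projected
through the region's filters, voxels are weighted by their band-power
share, and the pooling direction is the leading eigenvector of the
weighted region CSD. Using broadband covariance instead would let
low-frequency sensor noise dominate the pooling direction — in pilot runs
broadband PCA returned the common pink-noise mode rather than the
oscillatory source. The pooled time series itself remains broadband; its
sign is fixed by positive correlation with the peak-voxel series.

## MVAR, PDC and RPDC

`fit_var()` is ordinary multivariate least squares over concatenated
epochs with boundary-crossing lag windows excluded, degrees-of-freedom
corrected innovation covariance, a recorded stability check, and a small
ridge fallback (1e-6 of the mean regressor diagonal) for ill-conditioned
designs. `select_order_aic()` minimizes
`log det Sigma(p) + 2 p d^2 / T` on a common effective sample, ties going
to the smaller order. MVAR models are fitted on broadband pooled signals
and evaluated at band frequencies afterwards; band-filtering before
fitting is deliberately not done (filtering distorts the lag structure
Granger-type measures depend on).

PDC is the column-normalized magnitude of
`Abar(f) = I - sum_k A_k e^(-2 pi i f k / fs)`; the squared values sum to
one over targets for every source column and frequency, which every
computation asserts.

RPDC standardizes the two-vector `(Re Abar_ij, Im Abar_ij)` by its
covariance propagated from the least-squares estimator covariance
(innovation variance times the inverse regressor cross-product, mapped
through the lag cosine/sine loadings). The resulting quadratic form is
scale-invariant and, under the null of no coupling, approximately
chi-squared. Two practical notes:

* the two degrees of freedom require model order at least 2 — at order 1
  the real and imaginary loadings are collinear and the statistic has one
  degree of freedom;
* the statistic grows with the sample size under the alternative (it is a
  Wald-type statistic, not a bounded coherence), which is what makes the
  surrogate-mean threshold meaningful.

## DEKF and tPDC

Two coupled filters alternate at every sample: a state filter predicts the
next signal value from the current coefficient estimates and updates it
with the observed sample, and a coefficient filter (random-walk parameter
model) updates the stacked VAR coefficients using the lagged filtered
states as regressors. Coefficients are initialized from a stationary fit
on the first second; the first second is discarded as burn-in.

Tuning (all in `dekf_config()`):

* `q` (default 1e-5) — the coefficient random-walk process noise,
  normalized internally by the regressor power so that `q` fixes the
  filter's effective averaging window at about `1/sqrt(q)` samples
  (~316 samples, 1.2 s at 256 Hz) regardless of signal scale. An
  unnormalized process noise makes the effective window collapse to a few
  samples on high-variance near-unit-root oscillators, drowning the track
  in estimation noise. The default window satisfies both stationary
  consistency (time-averaged tPDC within 0.05 of static PDC per
  connection, on band means) and tracking (a mid-run coupling step is
  crossed within about 1 s, comfortably under 2 s).
* `r_state` (default 0.01) — the state filter's observation-noise scale
  relative to the innovation covariance. Small values treat the recording
  as near-noiseless observations; large values over-smooth the regressors
  and bias the coefficient track.

tPDC applies the PDC formula to the coefficient matrices at each retained
(optionally strided) time index. Band summaries are per-connection
band-mean time courses; `temporal_variability()` is their standard
deviation over time (population convention: a course of 0.1, 0.2, 0.3 has
SD 0.0816).

One regime dependence deserves emphasis. On noiseless high-Q resonators
the PDC column saturates: near the resonance the denominator is dominated
by the tiny diagonal term, so PDC sits near 1 whatever the coupling, and
coupling modulation barely moves the band-mean course. Mild observation
noise de-saturates the measure; heavy noise instead makes the fitted
coefficients wander (the VAR on signal-plus-noise is misspecified) and
masks the modulation. The modulated-versus-constant contrast is therefore
exercised at 25 dB SNR, inside the sensitive regime; at 10 dB the same
contrast is statistically invisible at these modulation depths. This is a
property of tPDC on near-deterministic oscillators, not of the filter
implementation.

## Surrogates and the time-reversal test

`bootstrap_threshold()` cuts the series into non-overlapping 1-s windows,
shuffles their order independently per channel (preserving marginal
spectra, destroying lagged cross-channel structure), refits the MVAR at
the same order and recomputes band-mean RPDC, 100 times by default. The
per-connection threshold is the **mean** over surrogates — a deliberately
lenient rule, kept as the default because it is the documented procedure —
with the empirical 95th percentile stored alongside (`rule = "p95"`).
Edges passing in both directions make a pair *bidirectional*, one
direction *unidirectional*, none *none*.

The TRT exploits the fact that genuinely lagged interactions reverse
direction under time reversal while instantaneous (volume-conduction)
effects do not: the asymmetry `delta = s(i<-j) - s(j<-i)` must flip sign
on time-reversed data. Because the RPDC statistic is approximately
noncentral chi-squared, the sampling SD of `delta` is about
`2 sqrt(s_ij + s_ji)`; an edge is only sign-tested when `|delta|` exceeds
`floor_scale` (default 3) times that, and otherwise reported as
*indeterminate* (`NA`) — a symmetric bidirectional pair has no meaningful
asymmetry to revert, and treating it as failed would silently delete true
bidirectional edges. The surrogate set's asymmetry SD also feeds the
floor when available.

A known limitation, found and verified during development: for coupled
**near-deterministic narrow-band resonators** the time-reversed process,
refitted at finite order, retains same-direction coupling (a 200k-sample
fit of the reversed coupled-resonator system still shows the forward
edge). Highly predictable signals are a documented failure mode of
time-reversal testing; the TRT behaves canonically on generic lag-coupled
VAR systems, which is what the validation suite uses for its sensitivity
checks.

## Features, statistics, classification

Per subject and band: `source_power` (band power of the strongest pooled
source), `coherence` (mean pairwise band coherence), `rpdc` and `tpdc`
(band means over ordered source pairs, self-connections excluded) — 20
named values. `group_statistics()` runs per-band two-sample t-tests with
Bonferroni adjustment, a factorial ANOVA over group/band/modality (factors
with a single level are dropped from the design), and a Friedman rank test
across bands with subjects as blocks; zero-variance cells short-circuit to
exact comparison with a note.

`svm_classify()` is a third-degree polynomial-kernel SVM (kernel scale
0.25, offset 1), soft-margin cost selected from `{1, ..., 10}` by an inner
cross-validation run **inside each training fold**, stratified 10-fold
outer CV repeated three times with reshuffling. Standardization uses
training-fold statistics only; the test suite includes a leak detector
(chance-labelled data must stay at chance) and a label-permutation
calibration. Accuracy is reported per measure block (5 band values each)
and for the full 20-feature vector. `simulate_feature_cohort()` draws
subject vectors from built-in group profiles with strong
theta/alpha/gamma contrasts and overlapping delta/beta — the separability
structure the classifier is expected to exploit.

## The pipeline

`run_pipeline(pipeline_config(...))` ties the stages together on a
simulated cohort; every stage draws its randomness from a named substream
of the single top-level seed, so reruns are bit-identical and stages can
be reproduced in isolation. Stage results (per-subject IAF, source maps,
measures, validated networks, the feature table, group statistics and the
classifier report) are returned in one `pipeline_result`; edge tables and
feature tables export as tab-separated text.

Default problem sizes are chosen for interactive use: the test suite runs
its pipeline smoke test at 2 subjects per group, 22 one-second epochs, 10
channels and a 6x6x6 5-mm grid, and the deeper simulation checks use
2-4-node systems with 4000-15000 samples. All defaults scale up by
configuration.

## Known limitations

* Scalar (fixed-orientation) beamformer on synthetic gains; no realistic
  forward model, no three-orientation dipole reduction.
* DICS-type filters partially cancel strongly correlated sources; the
  generator mitigates (distinct pole frequencies) but reciprocally locked
  same-band sources remain hard to separate, as they are for the method
  itself.
* TRT is unreliable on near-deterministic signals (see above).
* The RPDC chi-squared null is asymptotic; at very short series (a few
  hundred samples) the calibration degrades.
* The surrogate "mean" threshold rule is lenient by construction; `p95`
  is computed alongside and reported whenever thresholds are applied.
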