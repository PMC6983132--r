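---
title: "Quantifying kinetic tremor from circle drawings: models and methods"
author: "tremorkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying kinetic tremor from circle drawings: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Kinetic tremor — involuntary oscillation during voluntary movement — is a
common motor symptom of Parkinson's disease, typically in the 4–9 Hz band
and highly intermittent. Clinical ratings of tremor (UPDRS item 21, or
finer purpose-built visual scales such as a 0–10 *tremor score*) are
coarse and rater-dependent. An instrumented alternative records the pen
trajectory while the patient traces a 130 mm circle template on a
digitizing tablet (100 samples/s, pen pressure in 0–1023 device units,
about 100 s per recording) and maps signal-derived parameters to a
continuous tremor score.

`tremorkit` implements the full chain: a documented plain-text recording
format; expert ("time-series") parameters built on a spectral tremor
statistic, kinematics and entropy; reservoir-network ("ESN") parameters
that summarize how a fixed random recurrent network responds to the
drawing; LASSO score models on either parameter set; and mean-aggregated
model ensembles over a reservoir hyperparameter grid. Because no clinical
dataset ships with the package, a synthetic generator produces
circle-drawing recordings with controllable tremor; every result in the
test suite is computed on those synthetic study conditions.

## The spectral tremor statistic (tQ)

A tremor leaves a prominent narrow peak in the trajectory's spectrum. Per
recording:

1. `x(t)` and `y(t)` are high-pass filtered at 0.5 Hz and transformed with
   a short-time Fourier transform (Hann window of 512 samples, 5-sample
   step, 256 frequency bins).
2. The two spectrograms are combined as
   `STFTc(f,t) = |STFTx|^2 + |STFTy|^2`, so the statistic does not depend
   on the tremor's direction in the plane.
3. The spectrogram is cut into 2-s segments advancing by 0.05 s, and each
   segment's PSD `S_i(f)` is the mean of its spectrogram columns
   (Welch-style averaging of the already computed periodogram columns; no
   second transform).
4. The slow circle-tracing motion leaks a power-law background into each
   segment. A function `b |f|^-alpha` is fitted over 2–26 Hz by least
   absolute residuals in log-log coordinates — robust against the spectral
   peaks, which are exactly the outliers of this fit — and divided out,
   leaving the residual spectrum `S_T,i(f)`.
5. `S_T,i` is partitioned into 26 fixed half-Hz bins spanning 2–15 Hz. With
   bin powers sorted ascending into `W[1..26]`,
   `tQ_i = W[26] / mean(W[1..23])`: the dominant bin against the average
   background, with ranks 24–25 excluded because they may carry harmonics
   of the dominant peak. The centre frequency of the top bin is `f_tQ,i`.

tQ is a ratio, so it is invariant to trajectory scaling; the absolute
scaling convention of the STFT is therefore immaterial (we use one-sided
density scaling so that band-power checks against Parseval's theorem are
convenient).

Numerical choices: the L1 background fit is solved by iteratively
reweighted least squares on the log-log linear model (at most 50
iterations, weight floor 1e-8, early exit on convergence); `alpha` is
clipped at 0, and a flat or rising spectrum falls back to the L1-optimal
constant (the median log-power). The IRLS weights amplify float rounding
when residuals approach the floor, so scale invariance holds to about
1e-5 relative rather than machine precision. Bins are half-open with the
final edge closed, which makes the 26-bin partition exact; argmax ties
break toward the lower frequency. Segments with incomplete 2-s coverage
at the spectrogram edges are dropped, and an all-zero residual spectrum
is reported as a degenerate segment rather than a number.

## The 23 time-series parameters

The per-recording feature vector (see `featureNames()`) combines:

* total trajectory power above 3 Hz (Welch: 1024 frequency bins,
  1000-sample Hann window, 80% overlap) and its log10;
* the modal dominant-bin frequency `f_tQ_mod`, and its distance from 5 Hz
  (the centre of the kinetic-tremor band);
* mean, SD and CV of tQ over the segments covering the 10 s of recording
  with the highest tQ (200 segments at the 0.05 s step; a shorter
  recording uses all segments and flags the vector), with log10 variants;
* mean, SD and CV of the background exponent `alpha` over all segments;
* mean, SD, CV (and one log) of the absolute transverse velocity
  low-passed at 1 Hz;
* raw pen-pressure mean, SD and CV;
* multiscale sample entropy (m = 2, scales 5, 10, 25, 50) of the
  transverse velocity high-passed at 0.05 Hz.

"Transverse to the reference circle" is read as the radial direction from
the template centre: motion along the template is tangential, so tremor
appears as radial excursion. Velocity uses central differences (one-sided
at the ends), and the radial unit vector carries the previous direction
if the pen sits exactly at the centre.

The four log-transformed columns are frozen in the schema. They
correspond to the parameters whose raw distributions are heavily
right-skewed; the subsample-skewness screening that selects such columns
(mean skewness minus one SD above 3, over 100 random 60% subsets) is
available as the diagnostic `skewnessScreen()` but does not alter the
schema, so models trained on different datasets stay column-compatible.

All filters are linear-phase window-method FIRs (Hann), applied forward
and backward for zero net delay. Filtering is done in-package with
reflect-padded FFT convolution: zero-padded forward-backward filtering
would corrupt roughly 20 s of signal at the 2001-tap 0.05 Hz high-pass.
High-pass filters need even order (a type-II FIR high-pass has a forced
zero at Nyquist), so the 2000-sample window becomes order 2000 / 2001
taps; the unspecified 1 Hz low-pass uses 501 taps.

Sample entropy follows the standard template-counting definition:
`-ln(A/B)` with Chebyshev distance strictly below the threshold,
self-matches excluded. The similarity threshold is `0.15 * SD` of the
original (pre-coarse-graining) series — the usual multiscale convention;
no canonical threshold exists for tablet velocity signals, so it is an
exposed calibration knob. A series with no template matches at length
m+1 yields an infinite entropy; `assembleMatrix()` substitutes the
largest finite value in the column because a regularized linear model
cannot ingest infinities.

## Reservoir (ESN) parameters

An echo state network with `N` neurons updates its state as

```
x(t) = (1 - alpha) x(t-1) + alpha * tanh(Win [1; u(t)] + W x(t-1))
```

with `W` sparse (Bernoulli mask, expected proportion `s_W = 0.1` of
non-zero entries, values uniform on [-0.5, 0.5]) and `Win` uniform on
[-0.5ω, 0.5ω]. Under leaky integration the stability-relevant quantity is
the effective spectral radius `rho(alpha W + (1 - alpha) I)`.

The reservoir input is the drawing reduced to one channel: `x` and `y`
band-passed over 1–12 Hz (order-1000 Hann FIR, zero phase), decimated by
2, projected on their first principal component, and divided by the
component's interquartile range. The PC sign is fixed so the loading on
`x` is non-negative; otherwise the sign indeterminacy of PCA would flip
readout weights between runs. The *unnormalized* component is kept as the
readout target so the trained weights embed the original amplitude.

Each reservoir is characterized by two quantities:

* **Adjusted Lyapunov exponent.** The largest exponent is estimated by a
  finite-time two-trajectory experiment: reference and perturbed states
  (initial separation 1e-9 on one neuron) driven by the same uniform
  [-1, 1] noise, stepwise renormalization, 1000-step washout, 2000
  averaged steps. A collapse of the separation to exactly zero (possible
  when the perturbed neuron feeds no other neuron in a sparse reservoir)
  re-perturbs the next neuron and does not enter the average. The probe
  excites the network through *unit-scale* input weights rather than the
  member's own `Win`: at ω = 10 the member drive saturates the tanh so
  deeply that the exponent-radius relation becomes flat and non-monotone
  and the iterative adjustment (which assumes monotonicity) cannot reach
  its target at all; under standardized excitation the relation is clean
  for every grid configuration. The exponent is then steered to a target
  (grid values -0.2 and -0.05, tolerance 0.001) by iteratively nudging
  the effective spectral radius (initial step 0.05, halved when the
  deviation changes sign, at most 30 iterations, best iterate returned);
  if the tolerance is missed the reservoir is re-initialized, up to 5
  times. The defaults converge for all 54 grid configurations.
* **Memory capacity.** `MC = sum over k of r^2` between the k-delayed
  probe input and a linear readout trained to reconstruct it, delays
  1..2N, a 4000-step uniform probe after washout, ridge floor 1e-8 on the
  readout regressions. MC is theoretically bounded by N; the test bound
  allows +0.5 of estimation noise.

A note on the echo state property: a negative *local* exponent does not
guarantee the *global* property — near the edge of chaos a reservoir can
hold coexisting attractors, so two distant initial states never merge
even though perturbations around each attractor decay. Construction
therefore validates the property explicitly: `buildEsn()` runs
`echoStateCheck()` (two random initial states, same input, final distance
below 1e-6 over 2000 steps, under the probe realization that defines the
adjusted exponent) and re-initializes the reservoir when it fails, within
the same retry budget as the exponent adjustment. Two caveats remain
worth recording. First, for the edge-of-chaos target (-0.05) the
finite-time exponent varies across drive realizations by more than its
distance from zero, so convergence under an *independent* noise
realization is not guaranteed — a property of operating deliberately near
the stability boundary. Second, under a member's own drive at ω = 0.1 the
excitation can be too weak to engage the stabilizing saturation when the
adjusted radius exceeds 1, and trajectories need not converge. Neither
affects reproducibility: activations are always computed from the zero
state with a 100-step washout.

After running a recording through a reservoir, the `4N` activation
parameters are: per-neuron RMS activation, per-neuron activation SD, the
readout weights for one-step-ahead prediction of the unnormalized
component, and the readout weights for reconstruction of the component
`round(MC/2)` steps back (bias weights dropped; ordinary least squares
with a 1e-8 ridge floor; 100-step washout excluded).

## Score models and ensembles

Feature matrices `D_TS` (23 columns), `D_ESN` (4N columns) or their
combination are split 60/40 into train and test by stratified sampling on
the integer score (strata with fewer than 2 recordings merge into the
nearest score). A linear model is fitted by LASSO with the regularization
weight chosen by 10-times-repeated, stratified 5-fold cross-validation;
the mean CV MSE and its standard error pool all 50 fold-level MSEs.
`lambda_MIN` minimizes the mean CV MSE; `lambda_1SE` is the sparsest
model within one standard error of that minimum. Columns are standardized
inside the solver (the ESN and time-series scales differ by orders of
magnitude) and coefficients are reported on the original scale.

Predictions are passed through the limiting function `g`: identity on the
modelled scale (0–10 for the tremor score, 0–4 for UPDRS item 21) and a
`0.5 tanh` saturation outside, so outputs stay within half a point of the
scale.

Reservoir-based models are aggregated into ensembles over the
hyperparameter grid (N in {50, 100, 200}; Lyapunov targets -0.2, -0.05;
leaking rates 0.6, 0.9, 1; input scalings 0.1, 1, 10; 4 repetitions = 216
members, each with a freshly initialized reservoir). The signal-based
parameters are computed once and reused across members; only reservoirs
are re-initialized. The ensemble output averages the members' already
limited predictions — each member's model is defined with the limiter
attached, so averaging happens on the bounded scale.

## The synthetic generator and what it does (not) show

`simulateDrawing()` emulates the measurement: a 65 mm-radius circle
traced at 0.35 revolutions/s around the template centre, plus a
sinusoidal tremor of configurable amplitude and frequency applied along a
direction that rotates with a 50 s period (so both coordinates carry
tremor power), gated by a two-state Markov burst process (3 s mean burst,
configurable active fraction — the symptom is highly intermittent), plus
white positional jitter (0.2 mm SD default), a clipped-Gaussian pressure
channel, and optionally a 2-s off-template excursion artifact.
`simulateDataset()` draws amplitudes from a fixed 11-point grid — 0 mm,
then geometric from 0.1 to 8 mm — whose index is the ground-truth score
0..10, and draws each recording's tremor frequency uniformly from 4–9 Hz.

The generator provides a strictly monotone amplitude-to-score ground
truth, which is what the recovery tests need; it is *not* a claim about
clinical scoring, and it omits features of real data: no drift of the
drawing speed or circle centre, no bradykinesia or micrographia
morphology, no rater noise, no pressure-position coupling, and a single
sinusoidal tremor component rather than a harmonic stack. Passing the
recovery tests therefore shows that the pipeline can recover a known
monotone severity signal from realistic kinematics at realistic sampling
— not that it reproduces clinical correlation levels, which were
established on 1100 patient recordings that are not distributable.

## Study sizes used by the test suite

The synthetic recovery experiment uses 150 recordings at the full 100-s,
100 samples/s format, a stratified 60/40 split, and ensembles over the
reduced grid N = 50 with one repetition (18 members), re-initialized five
times; the time-series model is checked for test-set Pearson r above 0.8,
and the ensemble's spread (max - min r over the five re-initializations)
is compared against the spread of five individual reservoir models. These
sizes keep a laptop-scale run in minutes while leaving every stage at its
native resolution. Module tests use shorter recordings (12–40 s), which
the extractor flags (fewer than 200 segments) but processes identically.

## Known limitations

* The Lyapunov estimate and memory capacity are finite-time, seeded
  estimates; their values at different probe lengths differ slightly. All
  probe constants are exposed in `esnConfig()`.
* The L1 background fit is exact only up to IRLS convergence; spectra
  whose residuals sit at the weight floor inherit ~1e-5 relative
  sensitivity.
* Pressure statistics use the raw pressure channel; whether filtering
  should precede them is an open choice, and recordings without a
  pressure channel are imputed at 512 and flagged.
* The package scores kinetic tremor from circle drawings only; it does
  not classify disease state, handle spiral templates, or model
  handedness.
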