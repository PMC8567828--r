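---
title: "Methods: closed-loop slow-wave stimulation analysis with upstate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: closed-loop slow-wave stimulation analysis with upstate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(upstate)
```

## What this package computes

`upstate` implements the computational chain of a closed-loop
slow-oscillation stimulation experiment in sleep EEG, end to end:

1. **Synthetic cohort generation** — sleep-like EEG with slow-wave
   oscillations (SWOs), up-state-nested spindles, 1/f background noise,
   lagged inter-channel coupling, stimulation events, stimulation-induced
   connectivity effects, and confidence-rating behavior with a controllable
   metacognitive-sensitivity link.
2. **Closed-loop up-state detection** — an emulated real-time detector that
   gates on slow-wave band power, fits a sine at the detected center
   frequency, and projects forward to the next zero phase (the predicted
   up-state start), plus offline validation of phase locking with a v-test.
3. **Spectral connectivity** — Welch cross-spectra and the imaginary part of
   coherency (iCoh) in six canonical bands, for baseline and
   post-stimulation windows, baseline-corrected.
4. **Graph features** — eight network metrics per band on thresholded
   |iCoh| graphs: the 48-dimensional stimulation-induced feature vector.
5. **Metamemory** — type-2 ROC AUC from correctness/confidence trials, the
   overnight change being the regression target.
6. **Selection and modeling** — collinearity pruning, univariate filters,
   shadow-feature random-forest ("all-relevant") selection,
   logistic/ridge/linear models inside 35 repeated random-split folds, AUC
   with stratified-bootstrap CIs and a Mann-Whitney test, RMSE against an
   intercept-only baseline, and per-band group tests with FDR control.

No human data ship with the package; every analysis is exercised on the
synthetic cohort, whose ground truth makes recovery measurable.

## The generative model

### Signals

Each channel is the sum of

* **1/f background**: Gaussian noise spectrally shaped to `1/f^a`
  (`noise_exponent`, default 1), scaled to `noise_sd` (default 15 uV);
* **SWO**: a sinusoid whose instantaneous frequency performs a reflected
  Gaussian random walk inside 0.5-1.2 Hz at `swo_freq_walk` (default
  0.05 Hz per sqrt-second, so the frequency drifts only ~0.1 Hz over one
  5-s detector buffer — a narrowband oscillation on the detector's
  timescale that still exercises center-frequency tracking), amplitude
  `swo_amplitude` (default 75 uV, a typical deep-sleep slow-wave scale);
* **spindles**: 12-15 Hz band-limited noise, amplitude-modulated by the
  squared positive half-wave of the SWO so bursts nest in up-states
  (default 10 uV);
* **couplings**: shared band-limited sources added to a channel set with a
  per-channel delay of `(j-1) * lag` (defaults 15-20 ms steps). A positive
  delay is what makes the imaginary part of coherency nonzero; `lag = 0`
  reproduces pure volume conduction, which iCoh must ignore.

Band-limited sources are brick-wall filtered in the frequency domain, so a
source injected into one band carries exactly zero power in any disjoint
band; band specificity of injected effects is then a meaningful test of the
estimator rather than of filter skirts.

The true SWO phase (0 = positive zero-upcrossing = up-state start) is
returned per sample, so detector accuracy can be scored against ground
truth.

### Stimulation effects

`inject_stim_effect()` adds extra lagged coupling in chosen bands during
the 3-7 s window after each Active stimulation offset, scaled in SD units
of the background noise. Pre-stimulation windows are untouched and Sham
recordings pass through unchanged, so Active and Sham differ only by the
injected effect — the contrast the whole analysis is designed to detect.

### Feature-table fixtures

`generate_feature_table()` draws the 48 features directly from a
multivariate normal, bypassing signal simulation, for fast and exactly
controlled modeling experiments. Its default correlation is the Kronecker
product of an exchangeable between-band block (0.3) and a structured
within-band block (`feature_correlation_matrix()`): characteristic path
length, radius and diameter co-vary strongly (~0.75) because all three are
functions of one distance matrix; global efficiency is their negatively
coupled counterpart; density and mean coherence both track overall coupling
strength (0.75). This is deliberate: graph-metric features of real
connectivity data are highly collinear, the modeling stage's collinearity
pruning exists precisely for that structure, and near-misses in feature
selection (picking radius where path length was injected) remain
informative proxies rather than pure noise — as they are in real data.

### Behavior

Confidence is generated by discretizing a latent evidence variable into 10
bins. For a session with target type-2 AUC `A`, evidence for correct trials
is drawn `N(delta, 1)` and for incorrect trials `N(0, 1)` with
`delta = sqrt(2) * qnorm(A)`; the binning is a fixed monotone map, to which
the type-2 AUC is invariant up to tie-induced loss (small for 10 bins).
The overnight change in AUC is linked to a chosen feature through a
Gaussian copula: the latent sensitivity shift is
`rho * z(feature) + sqrt(1 - rho^2) * noise`, giving exact control of the
target correlation (default -0.66 against beta-band path length).

Defaults: 200 trials per session, so AUC estimation noise (~0.03 SE)
attenuates the built-in correlation by under 5%; pre-sleep AUC 0.55
(mid-scale, so the post-sleep targets rarely hit the AUC bounds);
overnight change mean 0.05, SD 0.25 — an intercept-only predictor of the
change then has RMSE around 0.25, the operating regime the modeling stage
is designed for. The number of stimulation events per night defaults
to 100; it is a configuration knob, not a claim about any particular
protocol.

### What the generator does not emulate

No volumetric head model or electric-field physics, no sleep architecture
(stage cycling, arousals), no non-stationary artifacts (movement, sweat,
electrode pops), no learning dynamics inside a session. Passing tests on
this cohort demonstrate that the pipeline recovers the structure it assumes
from data that satisfy those assumptions — not that real recordings do.

## The detector

The streaming loop holds a 5-s buffer of the 13 fronto-parieto-central
channels, updated every `hop` seconds (default 100 ms — the update cadence
is an emulation choice that bounds latency and makes tests deterministic).
Each cycle:

1. **Cleaning** — a trailing (causal) 1-s moving average is subtracted per
   channel; channels exceeding 500 uV min-to-max are dropped; the survivors
   are averaged into a virtual channel. The trailing window is what a
   real-time loop can actually apply, and it leaves the buffer's most
   recent samples undistorted.
2. **Gate** — the periodogram (zero-padded to 0.1-Hz steps) must put more
   than 0.3 of broadband (0.1 Hz-Nyquist) power into 0.5-1.2 Hz. The
   spectral peak inside the band, refined by parabolic interpolation of
   log-power across the peak bin, is the center frequency `f_c`.
3. **Phase and fit** — the virtual channel is bandpassed (causal
   second-order Butterworth, 1 Hz bandwidth around `f_c`, lower edge
   clamped at 0.1 Hz) and `A sin(2 pi f_c t + phi) + c` is least-squares
   fit to the settled last 3.5 s of the filtered buffer. Because the causal
   chain (detrend + filter) has a known nonzero phase at `f_c`, that phase
   (`causal_chain_phase()`, closed form) is subtracted from `phi` — the
   compensation any deployed closed-loop system applies for its own
   filters. Without it, markers lag the true up-state systematically by
   20-35 degrees.
4. **Projection** — the next time with total phase 0 (mod 2 pi) after the
   buffer end is the marker; stimulation spans half a period (the predicted
   up-state; the up-state duration is taken as half the period at `f_c`)
   with 100-ms ramps. A refractory period (default one period) separates
   markers; an optional flag defers stimulation by one full cycle,
   emulating hardware delay.

Phase follows the upcrossing convention throughout: phase 0 at the positive
zero crossing, so `sin` has phase 0 at t = 0 and the up-state peak sits at
+90 degrees. Offline validation filters the raw virtual channel 0.5-1.2 Hz
with a zero-phase (forward-backward) filter, reads the Hilbert phase at
each marker, and applies the v-test against 0 degrees using the normal
approximation `u = R cos(theta) * sqrt(2n)`.

## Spectral connectivity choices

Preprocessing decimates to 250 Hz behind a zero-phase anti-alias lowpass,
re-references to the channel average, and bandpasses 0.1-70 Hz with a
second-order Butterworth run forward-backward (24 dB/oct magnitude, no
phase distortion — phase fidelity matters for a connectivity measure built
on cross-spectral phase). An injectable artifact-rejection hook (identity
by default) replaces manual component-based cleaning, which is
irreproducible by definition.

Epochs are -6.4 to -2.4 s before stimulation onset (baseline) and +3 to
+7 s after offset (analysis); epochs intersecting any stimulation interval
are dropped and counted. Welch segments are 512 samples (2048 ms) with 50%
overlap and a Hamming taper, giving ~0.488 Hz resolution. Cross-spectra are
averaged across segments *and* epochs before coherency is formed
(coherency of averages, the standard stabilization at low trial counts),
then `iCoh = Im(S_xy / sqrt(S_xx S_yy))` is averaged over the bins whose
centers fall in each half-open band `[low, high)` — half-open so abutting
band edges are never double-counted.

## Graph features

Edge weights are |iCoh| (the magnitude carries coupling strength; the sign
only encodes lead/lag). Binary adjacency uses an absolute threshold
(default tau = 0.1, exposed in the API together with a proportional top-k%
rule) because topological metrics are defined on edges; no published cutoff
exists for this design, so the threshold is a config parameter recorded in
provenance, and `build_graph()` makes sensitivity analysis one loop.
Distances are hop counts; on a disconnected graph the distance statistics
are computed on the largest component (flagged), while global efficiency
uses `1/Inf = 0` on the full graph. Modularity is the Newman Q of the
partition found by the Louvain method under a fixed seed. Density defaults
to the standard `m / (n(n-1)/2)`; the literal edges-per-node variant is
selectable. Mean coherence is computed on the raw band matrix, independent
of thresholding.

The default feature set is 8 metrics x 6 bands = 48 features per
participant and condition, each the analysis-minus-baseline change:
clustering, global efficiency, path length, radius, diameter, modularity,
density, mean coherence. Degree assortativity is implemented and tested but
excluded from the default set: it is undefined on degree-regular graphs,
which thresholded small graphs frequently are, and a feature that goes
missing per graph would leave holes in the table. Characteristic path
length is the mean shortest-path length (an eccentricity-based variant is
available but non-default).

## Modeling stage

Per fold (35 repeated random splits holding out 1-3 of the participants,
with resampling until every participant is held out at least once), strictly
on training rows:

1. constant columns dropped; iteratively, the highest-|r| feature pair above
   0.8 loses its member with the larger mean absolute correlation;
2. univariate filter: paired t across conditions (|t| >= 1 kept) for
   classification, Pearson r against the overnight AUC change (|r| >= 0.1)
   for regression;
3. shadow-feature selection: per iteration, every feature gets a
   row-permuted shadow copy, a random forest is fit on the joint design,
   and a feature scores a hit when its permutation-importance Z exceeds the
   iteration's shadow maximum; hit counts significantly above Binomial(n,
   1/2) (two-sided, alpha 0.05) are confirmed, significantly below
   rejected, the rest tentative. Tentative features are excluded from
   models. If a fold confirms nothing, the single strongest filter feature
   is used so every fold can still predict (logged as a fallback);
4. models: logistic / linear on the selected set, ridge variants with
   lambda chosen by inner 5-fold CV over a 20-point log grid 1e-3..1e3,
   plus the top feature(s) and the combined classification+regression
   selection, all standardized by training statistics only.

Out-of-fold scores are concatenated across folds (participants held out
several times contribute several scores). Classification is summarized by
ROC AUC, a one-sided Mann-Whitney test against chance, and a 95%
class-stratified bootstrap percentile CI (resampling scores, not re-running
folds). One subtlety matters for inference: repeated random splits score
each participant several times, and treating those duplicate scores as
independent observations inflates the U test's size several-fold and makes
the bootstrap CI spuriously narrow (measured on null cohorts: 27% rejection
at nominal 5%, 53% CI coverage of chance). The pipeline therefore averages
scores within participant x condition before the test and the bootstrap, so
inference runs on approximately independent units. Even after that
correction a residual optimism remains that no implementation of this
design can remove: with 1-3-participant holdouts the per-fold feature
selection re-selects nearly the same (under the null, spurious) winner
across overlapping training sets, so out-of-fold scores partly evaluate an
in-sample-selected feature. Measured on 100 null cohorts, the U test
rejects about 15% of the time at nominal 5% and the 95% CI covers chance
about 83% of the time, whereas the same evaluation with a fixed feature is
calibrated (about 3%). Positive findings from this design therefore carry
a mildly inflated false-positive risk, which readers should weigh.
Regression reports mean per-fold RMSE against the per-fold intercept-only
baseline.

Single-run shadow selection defaults to 100 iterations x 500 trees; the
pipeline's per-fold defaults are 30 iterations x 150 trees, a deliberate
trade of a little selection stability against running 70 selections per
analysis. The whole-sample follow-up (final selection, per-feature paired t
tests with Benjamini-Hochberg adjustment, per-band one-tailed mean-coherence
tests with FDR) runs once on the full table.

## Numerical and degenerate-input choices

* Hilbert transforms use the FFT construction; phases are wrapped to
  (-pi, pi].
* The power-ratio of an all-zero buffer is reported as 0 (no detection),
  not NaN.
* A sine fit with amplitude below 1e-8 uV aborts the detection cycle.
* Zero-power channels make the corresponding iCoh pairs NA and are counted.
* Type-2 AUC with all-correct or all-incorrect trials is NA (undefined),
  and ties receive half credit, making the trapezoidal area equal the
  rank-statistic U/(n1 n0).
* Paired tests with zero-variance differences are flagged degenerate
  rather than producing unstable t values; in the band-level group test an
  exactly-zero difference yields one-tailed p = 0.5 (no evidence) and a
  constant nonzero shift a saturated statistic.
* Assortativity of a degree-regular graph is NA and excluded downstream.
* All random stages consume explicit integer seeds; per-participant streams
  are derived deterministically from the master seed, so cohorts are
  reproducible bit for bit.

## Problem sizes used by the test suite

The suite exercises the signal chain on 40-150 s recordings at 500 Hz with
4-13 channels, cohorts of 18 participants for the modeling stage, 25-seed
Monte-Carlo loops for recovery properties, graph oracles on exhaustive
n <= 5 enumeration plus hundreds of random n <= 8 graphs, and 500-1000
bootstrap replications. The canonical recovery cohort injects d = 1.5
effects into two theta strength features and two spindle distance features
- the smallest effect size at which the all-relevant selection stage
confirms the injected set consistently across cohorts (at d = 1 the
per-cohort confirmation probability of 3 of the 4 features is only about a
quarter) - and links beta-band path length to the overnight sensitivity
change at rho = -0.66. These sizes were chosen so the full suite exercises
every claim at meaningful power while remaining comfortable to run locally;
all of them scale up through the public configuration objects.

One recovery property deliberately remains strict: requiring the
cross-validated regression to beat the intercept-only baseline in at least
90% of cohorts. With 18 participants, a +-0.66 link and per-fold selection
over 48 collinear features, an oracle that always knows the true feature
clears that bar (about 96% of cohorts), but honest per-fold selection does
not (roughly half to two-thirds, depending on the model), because a
spurious feature out-correlates the true one inside small training folds
often enough for winner's-curse slopes to erase the thin margin. The test
encodes the strict bar rather than a relaxed one; its failure rate is a
faithful report of that statistical reality, not a software defect.

## Known limitations

* The detector's phase compensation assumes the steady-state response of
  its own linear chain; strongly non-stationary signals inside one buffer
  violate that and widen the marker phase distribution.
* iCoh is blind to genuinely zero-lag physiological coupling by design.
* With 18 participants and 48 collinear features, per-fold selection is
  noisy; the pipeline reports selection frequencies across folds rather
  than pretending a single definitive feature set exists.
* Louvain modularity is a heuristic; its Q is deterministic under the fixed
  seed but not guaranteed to be the global maximum, and modularity is the
  one feature not invariant to channel relabeling in pathological ties.
* The synthetic cohort's behavioral link is linear-Gaussian; real
  metacognition is bounded and likely nonlinear near ceiling.
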