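---
title: "Methods: task-locked iEEG network dynamics with ieegnet"
author: "ieegnet authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: task-locked iEEG network dynamics with ieegnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ieegnet)
```

## Scope and data model

`ieegnet` analyses task-locked activation and connectivity dynamics in
intracranial EEG (stereo-EEG) recordings of a sequential cognitive task in
which seven stimuli (three operands N1--N3, two operators O1/O2, an equals
sign and a proposed result) are presented for 1.05 s each, preceded by a
fixation cross whose duration is jittered uniformly in [1.05, 1.55] s.
The package covers the full chain from the continuous multichannel signal to
region-of-interest (ROI) level summaries:

1. preprocessing (anti-alias downsampling, bipolar referencing, drift and
   line-noise filtering, epileptic-spike masking),
2. trigger-based trial extraction into a time x channel x trial tensor,
3. multitaper time-frequency decomposition with baseline z-score
   normalization,
4. high-gamma-band (HGB, 52--120 Hz) activation profiles, per-channel
   indicators, stimulus-period contrasts and peak-latency ordering,
5. time-resolved phase-locking-value (PLV) connectivity with onset/peak/
   offset detection, ROI-pair pooling and network-state snapshots.

Because raw clinical recordings cannot ship with a package, a first-class
synthetic-data module emulates the task with known ground truth, so every
stage is validated by parameter recovery rather than by fixture files.

## Preprocessing

Recordings sampled at 2048 Hz are low-pass filtered with an 8th-order
Chebyshev type I filter (cutoff 400 Hz) and decimated by an integer factor
to 512 Hz. The passband ripple is not a free scientific parameter; we fix
it at 0.05 dB, a standard decimation-filter default with negligible
passband distortion.

Bipolar channels are derived along each electrode shank by subtracting each
contact from its closest neighbour, starting from the deepest contact
(contact index 1), so a shank with n contacts yields n - 1 channels. This
cancels signal components common to the whole shank exactly (to machine
precision), which the test suite asserts. A bipolar channel inherits an ROI
if at least one of its two contacts lies in the ROI (the deeper contact's
assignment takes precedence when both are assigned).

All subsequent filters are zero-phase: the filter runs forward and backward,
squaring its magnitude response and cancelling its phase. Two numerical
choices matter here:

* The 0.1 Hz, 6th-order Butterworth high-pass is unstable in double
  precision when realized as a single transfer function at 512 Hz (its
  poles sit within 1e-3 of the unit circle and the expanded polynomial
  coefficients lose the information). We therefore design it analytically
  as cascaded second-order sections from the Butterworth prototype poles
  and run each biquad zero-phase. Channels are demeaned before the
  high-pass, which removes the DC step that would otherwise dominate the
  edge transients.
* Edge transients are controlled by odd-reflection padding whose length is
  derived from the slowest pole radius of the design (about seven time
  constants), capped at the signal length.

Band-stop filters at 48--52, 98--102 and 148--152 Hz remove line noise and
its harmonics; "6th order" band filters are realized as `butter(3, ...)`
(band transforms double the prototype order). Stop bands at or above the
Nyquist frequency are skipped.

Epileptic-spike handling is consumption, not detection: curated annotations
(channel, time) are applied with `applySpikeMask()`, which marks the closed
0.5-s window centred on each spike as rejected. Masking never alters signal
values; masked samples propagate as missing values into every downstream
average, so a spike removes the analysis windows it touches without
discarding whole trials. A simple amplitude-threshold detector
(`detectSpikes()`) is provided for convenience and labelled as a heuristic;
it is not a validated clinical detector.

## Epoching

Trials are extracted in the window [-2, 9] s around the onset of the first
operand N1 (t = 0). The window is deliberately wider than the analysis
range so that narrowband filtering of the trials has edge material; results
are cropped to [-1, 6] s afterwards. Windows are sample-inclusive at both
ends, so [-2, 9] s at 512 Hz holds exactly 5633 samples and [-1, 6] s
exactly 3585. The anchor is configurable (`anchor = "O1"`) because figure
conventions sometimes place t = 0 at the first operator; the operative
definition used throughout this package is the N1 anchor.

## Spectral decomposition and normalization

Time-frequency power is estimated with a sliding multitaper: 0.5-s windows,
two Slepian tapers, hop 16 samples (exactly 31.25 ms at 512 Hz). With K = 2
tapers we use a time-bandwidth product NW = 1.5 (K = 2NW - 1), giving about
+-3 Hz spectral concentration over the 0.5-s window. The 256-sample window
at 512 Hz natively yields the 2 Hz bin grid 0, 2, ..., 120 Hz through the
256-point FFT, so no zero padding is needed; bins are centers. No installed
R package provides Slepian tapers, so they are computed from the standard
symmetric tridiagonal eigenproblem and cached; unit energy and
orthogonality are asserted in the tests.

Power is converted to dB (10 log10, reference 1 uV^2) to reduce the skew of
the power distribution, then z-scored per frequency bin and channel against
the baseline interval t in [-1, -0.25] s (the fixation period), pooling all
baseline windows of all trials, and scaled by 100:

$$normPSD(t,f,ch,tr) = 100 \cdot \frac{rawPSD(t,f,ch,tr) - \mu(f,ch)}{\sigma(f,ch)}$$

so baseline activity has mean 0% and SD 100% by construction in every bin
-- this contract is asserted to 1e-6 on arbitrary synthetic input. The
z-score flattens the 1/f decay of the iEEG spectrum and puts channels on a
common scale. A constant-power input has sigma = 0 and is rejected with an
error naming the degenerate bin. Windows overlapping trial edges are
dropped rather than padded; windows containing masked samples are missing
for that channel and trial.

## High-gamma dynamics

HGB activity is the mean of the normalized spectrogram over the 52--120 Hz
bins whose +-1 Hz extent avoids the notched 100 Hz harmonic band (32 bins;
the 50 Hz harmonic lies below the band edge). Averaging hierarchy follows
the estimation logic of grand averages: average across trials per channel
first ("single-channel, trial-averaged HGB"), then across all channels of
all subjects in an ROI. Significance against baseline comes in two named
flavours, matching how such masks are normally reported:

* ROI masks: at each time point, the distribution of trial-averaged channel
  values against the pooled baseline values of the same channels (two-sided
  Wilcoxon rank-sum), FDR-corrected across time points; default alpha
  0.001.
* Per-channel duration indicator T(ch): at each time point, the
  across-trial distribution against the channel's pooled single-trial
  baseline values, FDR-corrected across all time points and channels;
  default alpha 0.05.

The two alphas are deliberate defaults of the respective conventions and
are config keys. The three per-channel indicators over [0, 5] s are M(ch),
the time-mean absolute trial-averaged HGB; T(ch), the summed duration of
significant time points; and b(ch), the ordinary least-squares slope of the
trial-averaged series on time.

Stimulus-period contrasts (N1 vs N2, N1 vs N3, N2 vs N3, O1 vs O2) use the
paired two-tailed sign test across channels on period means over the full
[onset, onset + 1.05) s presentation window, FDR-corrected across all
ROI x pair tests. Ties are dropped before the binomial, the standard sign
test convention.

The activation cascade is summarized by peak-latency ordering: per operand
period, ROIs whose ROI-level peak exceeds 2 baseline SDs (200% in
normalized units -- since the baseline SD is 100%, "2 of the baseline
distribution" is 200%) are ordered by the latency of their maximum (ties to
the earliest point). Pairwise latency differences are tested on the
distributions of single-channel peak latencies (rank-sum, FDR). The default
alpha is 0.05; the stricter 0.001 used by some displays is a config value.

Condition contrasts cover numerical format (with the matrix of Pearson
correlations between format-specific time courses as a similarity index),
operator sign, and decade crossing. For decade crossing the paired
difference per channel is formed within difficult trials between the
crossing operand's period and the non-crossing operand's period of the same
trial, which removes trial-level amplitude variability.

## PLV connectivity

Connectivity uses the filter--Hilbert approach: trials (on the full [-2, 9]
s window, to protect the edges) are band-pass filtered (Butterworth, 6th
order, zero-phase) in narrow bands -- delta 0.1--3, theta 3--7, alpha
7--12 Hz, then 4-Hz bands to 120 Hz -- and the instantaneous phase is the
argument of the analytic signal. For a channel pair (m, n) the
phase-locking value at time t is

$$PLV(m,n,t,f) = \frac{1}{N}\left|\sum_{tr=1}^{N} e^{i[\varphi(m,t,f,tr) - \varphi(n,t,f,tr)]}\right| \in [0,1],$$

computed only between channels of the same subject. Phases are computed at
the full 512 Hz and the PLV series is evaluated on the same 31.25-ms hop
grid as the spectrograms, so activation and connectivity share one time
axis. The PLV series is z-scored per pair and narrow band against its own
baseline-interval values and scaled to percent (the same convention as the
power normalization), and only then averaged over a named frequency range;
this order follows the estimation sequence normalization-then-band-average.
ROI-pair series are means over qualifying within-subject channel pairs, and
a connection is reported absent unless at least two subjects contribute
pairs. The global network PLV is the mean +- SEM over all pairs with a
per-time-point rank-sum test against pooled baseline values, FDR-corrected
over time points.

Onset, peak and offset of a connectivity bump are defined as the maximum of
the smoothed first derivative, the local maximum of the series, and the
minimum of the smoothed derivative within each operand period. The
derivative is a three-point central difference smoothed by a zero-phase
5 Hz Butterworth low-pass interpreted in the hop-grid sampling rate
(32 Hz). An onset additionally requires a positive derivative at its
maximum and an offset a negative one, both as interior local extrema: a
monotone ramp therefore has a peak at the period end but no offset. On a
Gaussian bump of SD s centred at c, the detected onset/offset fall at
c -+ s (the analytic extremes of the Gaussian derivative), which the
acceptance suite asserts to within one hop.

The strongest connections are ranked by their maximum normalized PLV within
a period; pairs must exceed 3 baseline SDs (300%) to enter, the top 15 are
kept and ordered by the latency of the maximum. Network states snapshot the
per-ROI HGB (nodes) and per-pair PLV (edges) at each detected time point,
scaled to the 1st--99th percentile of all values in [0, 6] s and clipped to
[0, 1]; a degenerate percentile range maps everything to 0 with a warning.

## Statistics

Scalar tests wrap the base R implementations: `wilcox.test` (exact
enumeration when both groups have at most 10 observations and no ties,
normal approximation with tie and continuity correction otherwise),
`binom.test` for the paired sign test, and `p.adjust` for
Benjamini--Hochberg (default) or Benjamini--Yekutieli FDR. The large
per-time-point families use a vectorized tie-corrected normal-approximation
rank-sum that is cross-checked against `wilcox.test` in the tests, keeping
the dual route between implementation and oracle. Each correction's family
follows its reporting scope: over time points for ROI masks and the global
PLV, over time points x channels for the duration indicator, over
ROI x pair tests for the period contrasts.

## The synthetic-data generator

`simulateSubject()` builds a channel-level continuous recording as the sum
of:

* a 1/f background (`makePinkNoise`, default exponent 1, RMS 20 uV),
  spectrally shaped white noise rescaled to the requested RMS exactly;
* per-ROI event-related potentials: a damped half-sine (default width
  0.35 s, i.e. content below 7 Hz) after each stimulus onset;
* per-ROI high-gamma bursts: Gaussian amplitude envelopes (SD =
  duration/2) modulating independent 52--120 Hz band-limited noise, locked
  to a stimulus role at a fixed latency;
* narrowband phase couplings between ROI pairs: a shared carrier at the
  band center added to both ROIs inside a per-trial window, with a von
  Mises-distributed phase difference whose concentration kappa solves
  I1(kappa)/I0(kappa) = target PLV (kappa = Inf collapses to identical
  phases, kappa = 0 to uniform). The von Mises sampler is the Best--Fisher
  rejection algorithm, checked against the resultant identity by Monte
  Carlo;
* optional epileptiform spikes: 70-ms biphasic transients at Poisson times,
  which exercise the 0.5-s mask-rejection path.

The task schedule defaults are the study conditions: 1.05-s stimuli,
fixation U(1.05, 1.55) s, four numerical formats, an 83% correct-response
rate and reaction times of 1.0 +- 0.4 s; feedback padding (0.5 s) is a
generator convention.

Burst amplitudes are specified in baseline-SD units of the normalized HGB
series, i.e. an amplitude of 3 targets a 300% peak. The calibration is
analytic: a K-taper dB power estimate has per-bin baseline SD
(10/ln 10) * sqrt(trigamma(K)) (about 3.49 dB for K = 2), so an amplitude-a
burst must raise in-band power by a times that many dB at the window
center; the injected gain additionally compensates the window-averaged
Gaussian envelope. Under this convention the injected component's RMS is a
deterministic, nonlinear function of the amplitude parameter, and the test
suite asserts that the measured gain ratio between two amplitudes matches
the closed form (the linearity check appropriate to a dB-calibrated scale).
Recovery tests on the full pipeline show 3-SD bursts peaking near 300% with
peak latencies recovered within one 31.25-ms hop.

The generator emulates the features the pipeline measures -- task-locked
power bursts, phase coupling, 1/f background, spikes -- but not volume
conduction, a common reference, non-stationary background, eye or muscle
artifacts, or biophysically realistic field potentials. Passing recovery
tests therefore demonstrates the estimators' correctness and calibration,
not robustness to every artifact of clinical data. Because bursts and
couplings are injected at the derived-channel level, the bipolar
referencing step is exercised separately on contact-level synthetic
fixtures (a burst common to two adjacent contacts would otherwise cancel by
construction).

## Problem sizes and determinism

The test and acceptance workloads are sized to what the estimators need,
not more: the latency-cascade study uses 4 ROIs x 1 channel x 100 trials
per simulation with 100 seeded replicates (the acceptance script reports
the same study over 30 replicates); PLV calibration uses 200 trials; FDR
calibration uses hundreds of null replicates of the vectorized test family.
All randomness flows from explicit integer seeds, and a fixed seed gives
byte-identical simulated sessions; `runPipeline()` reruns are
byte-identical in their numeric outputs.

## Known limitations

* Directed or effective connectivity, cross-frequency coupling and
  surrogate-based PLV bias correction are out of scope; the baseline
  z-scoring is the only bias handling for the PLV.
* The delta band's 0.1 Hz lower edge limits the numerical conditioning of
  its band-pass filter; phases there are reproducible to about 1e-3 rad
  under amplitude rescaling (theta and above reach 1e-6).
* EDF support covers continuous 16-bit recordings with uniform per-signal
  rates; BrainVision support covers multiplexed IEEE float / int16 binary.
  The plain float32 + JSON-sidecar container is the primary interchange
  format.
* Electrode localization and ROI atlas assignment are upstream of this
  package: channels arrive with ROI labels.
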