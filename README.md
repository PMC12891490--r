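# ieegnet

Task-locked network dynamics in intracranial EEG (stereo-EEG): high-gamma
activation profiles and time-resolved phase-locking connectivity, with a
ground-truth synthetic-task generator for validation by parameter recovery.

## The problem

Depth-electrode (SEEG) recordings during sequential cognitive tasks — here
a sequential arithmetic task in which three operands (N1–N3), two operators
(O1, O2), an equals sign and a proposed result are each shown for 1.05 s —
allow millisecond-scale tracking of *where* and *when* brain regions
engage. Two complementary views are standard:

* **Activation**: high-gamma-band power (HGB, 52–120 Hz) as a proxy for
  local population activity, expressed per region of interest (ROI) as a
  percent of the pre-stimulus baseline distribution;
* **Connectivity**: the phase-locking value (PLV) between channel pairs in
  low-frequency bands (delta 0.1–3 Hz, theta 3–7 Hz), which measures
  across-trial phase consistency independent of amplitude.

`ieegnet` implements the full chain for both views, for researchers who
analyse event-locked iEEG: preprocessing (anti-alias downsampling, bipolar
referencing, 0.1 Hz drift and 50/100/150 Hz notch filtering — all
zero-phase — and epileptic-spike masking), trial extraction, multitaper
spectrograms, HGB dynamics with per-channel indicators and peak-latency
ordering of the activation cascade, and PLV connectivity with
onset/peak/offset detection and network-state snapshots.

## The core quantities

Power in dB from a sliding two-taper (Slepian) estimate with 0.5-s windows
and a 31.25-ms hop is z-scored per frequency bin *f* and channel *ch*
against the fixation baseline *t* ∈ [−1, −0.25] s and scaled to percent:

    normPSD(t,f,ch,tr) = 100 · (rawPSD(t,f,ch,tr) − μ(f,ch)) / σ(f,ch)

so the baseline has mean 0% and SD 100% by construction. HGB(t,ch,tr) is
the mean of normPSD over the 52–120 Hz bins (excluding the notched 100 Hz
harmonic bins). For channels *m*, *n* of one subject with instantaneous
narrowband phases φ,

    PLV(m,n,t,f) = (1/N) |Σ_tr exp(i[φ(m,t,f,tr) − φ(n,t,f,tr)])| ∈ [0, 1],

then z-scored against its own baseline the same way. ROI values are grand
averages: trial-average each channel, then average channels across
subjects; ROI-pair connections require pairs from at least two subjects.

Because clinical recordings cannot ship with a package, a first-class
simulator (`simulateSubject()`) emulates the task with known ground truth —
1/f background, event-related potentials, calibrated HGB bursts
(amplitudes in baseline-SD units), von Mises phase couplings with a target
PLV, epileptiform spikes — so every estimator is validated by recovering
what was injected.

## Worked example

Simulate one subject with a four-ROI activation cascade (bursts 3 baseline
SDs strong, latencies 150/250/400/600 ms after N1) and one theta coupling,
then recover both:

```r
library(ieegnet)

rois <- c("IPS", "pITG", "MOG", "SPL")
truth <- groundTruth(
  bursts = burstSpec(roi = rois, role = "N1",
                     latency = c(0.15, 0.25, 0.40, 0.60),
                     duration = 0.3, amplitude = 3),
  couplings = couplingSpec(roiA = "IPS", roiB = "MOG", band = c(3, 7),
                           plv = 0.9, role = "N1", window = c(0.1, 0.9)))
montage <- data.frame(subject = "s01", channel = paste0(rois, "_1"), roi = rois)
sim <- simulateSubject(taskSchedule(nTrials = 30), truth, montage, seed = 7)

trials  <- extractTrials(sim@recording, sim@events, c(-2, 9))
cropped <- cropTrials(trials, c(-1, 6))
spec    <- baselineNormalize(multitaperSpectrogram(cropped), c(-1, -0.25))
hgb     <- extractHgb(spec)

latencyOrdering(hgb, periods = "N1", threshold = 200)$N1$ordering
#>    roi   latency     peak
#> 1  IPS 0.1552734 293.7675
#> 2 pITG 0.2490234 299.0124
#> 3  MOG 0.4052734 301.6834
#> 4  SPL 0.6240234 285.6970

plv   <- normalizePlv(plvConnectivity(trials), c(-1, -0.25))
theta <- bandAverage(plv, "theta")
g     <- globalPlv(theta)
tw    <- g$time >= 0 & g$time <= 1.05
cat(sprintf("theta PLV peak: %.0f%% of baseline SD at %.2f s\n",
            max(g$plv[tw]), g$time[tw][which.max(g$plv[tw])]))
#> theta PLV peak: 256% of baseline SD at 0.34 s
```

The ordering recovers the injected cascade: all four ROIs cross the 200%
(2 baseline SD) activation threshold, their order matches the injected
latencies, and each peak latency lands within one 31.25-ms hop of the
injection (the 3-SD amplitude calibration puts the peaks near 300%). The
theta-band global PLV rises far above its baseline inside the coupling
window. `runPipeline()` wraps this whole flow (multi-subject, both bands,
indicators, top-pair ordering, network states) behind a single config, and
`inst/scripts/ieegnet-cli.R` exposes `simulate` and `pipeline` subcommands
for shell use.

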