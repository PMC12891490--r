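Package: ieegnet
Title: Task-Locked Intracranial EEG Network Dynamics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis of task-locked network dynamics in intracranial EEG
    (stereo-EEG) recordings: anti-alias downsampling, bipolar referencing,
    drift and line-noise filtering, epileptic-spike masking, trigger-based
    trial extraction, multitaper time-frequency decomposition with baseline
    z-score normalization, high-gamma-band (52-120 Hz) activation profiles
    with per-channel indicators and peak-latency ordering, and time-resolved
    phase-locking-value connectivity with onset/peak/offset detection and
    network-state summaries. Includes a synthetic-data generator that
    emulates a sequential arithmetic task with known ground truth (burst
    latencies, coupling strengths, event schedule) so that every stage is
    verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
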