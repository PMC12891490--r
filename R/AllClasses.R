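# S4 class definitions for the continuous, epoched, spectral and
# connectivity containers, plus the simulation ground-truth objects.

## ---- simulation -----------------------------------------------------------

#' TaskSchedule: timing and condition structure of the sequential task
#'
#' Describes the sequential arithmetic task: each trial presents a fixation
#' cross (uniformly jittered duration), then seven stimuli (three operands
#' N1-N3, two operators O1/O2, an equals sign and the proposed result), each
#' shown for a fixed duration, followed by the subject's response and
#' feedback.
#'
#' @slot nTrials number of trials.
#' @slot stimulusDuration stimulus presentation time in seconds (1.05 s).
#' @slot fixationRange two-element range (s) of the uniformly jittered
#'   fixation-cross duration.
#' @slot roles ordered stimulus labels within a trial.
#' @slot formats numerical formats sampled per trial.
#' @slot difficulty `"easy"` or `"difficult"` (difficult trials carry a
#'   decade crossing at N2 or N3 with equal probability).
#' @slot correctRate probability of a correct response.
#' @slot rtMean,rtSd mean and SD (s) of the simulated reaction times.
#' @slot feedbackDuration padding (s) after the response before the next
#'   trial's fixation.
#' @exportClass TaskSchedule
setClass("TaskSchedule", slots = c(
  nTrials = "integer",
  stimulusDuration = "numeric",
  fixationRange = "numeric",
  roles = "character",
  formats = "character",
  difficulty = "character",
  correctRate = "numeric",
  rtMean = "numeric",
  rtSd = "numeric",
  feedbackDuration = "numeric"
))

setValidity("TaskSchedule", function(object) {
  msg <- character()
  if (object@nTrials < 1L) msg <- c(msg, "nTrials must be >= 1")
  if (object@stimulusDuration <= 0) msg <- c(msg, "stimulusDuration must be positive")
  if (length(object@fixationRange) != 2L || diff(object@fixationRange) < 0 ||
      any(object@fixationRange <= 0))
    msg <- c(msg, "fixationRange must be an increasing positive pair")
  if (object@correctRate < 0 || object@correctRate > 1)
    msg <- c(msg, "correctRate must lie in [0, 1]")
  if (object@feedbackDuration < 0) msg <- c(msg, "feedbackDuration must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a TaskSchedule
#'
#' Defaults reproduce the sequential arithmetic task conditions: 1.05 s
#' stimuli, fixation jittered uniformly in [1.05, 1.55] s, roles
#' N1,O1,N2,O2,N3,EQ,RESULT, four numerical formats, 83% correct responses
#' and reaction times of 1.0 +- 0.4 s.
#'
#' @param nTrials number of trials (default 40).
#' @param stimulusDuration seconds (default 1.05).
#' @param fixationRange seconds, uniform jitter range (default c(1.05, 1.55)).
#' @param roles ordered stimulus roles.
#' @param formats numerical format labels sampled per trial.
#' @param difficulty `"easy"` or `"difficult"`.
#' @param correctRate probability of a correct answer (default 0.83).
#' @param rtMean,rtSd reaction-time mean and SD in seconds (defaults 1.0, 0.4).
#' @param feedbackDuration post-response padding in seconds (default 0.5).
#' @return A [TaskSchedule-class] object.
#' @examples
#' sched <- taskSchedule(nTrials = 10)
#' @export
taskSchedule <- function(nTrials = 40L,
                         stimulusDuration = 1.05,
                         fixationRange = c(1.05, 1.55),
                         roles = c("N1", "O1", "N2", "O2", "N3", "EQ", "RESULT"),
                         formats = c("arabic", "word", "dice", "fingers"),
                         difficulty = "easy",
                         correctRate = 0.83,
                         rtMean = 1.0, rtSd = 0.4,
                         feedbackDuration = 0.5) {
  if (stimulusDuration <= 0) stop("invalid schedule: non-positive stimulusDuration")
  new("TaskSchedule", nTrials = as.integer(nTrials),
      stimulusDuration = stimulusDuration, fixationRange = fixationRange,
      roles = roles, formats = formats, difficulty = difficulty,
      correctRate = correctRate, rtMean = rtMean, rtSd = rtSd,
      feedbackDuration = feedbackDuration)
}

#' GroundTruth: injected structure of a simulated session
#'
#' Holds what the generator injects on top of the 1/f background so that the
#' downstream pipeline can be validated by parameter recovery: high-gamma
#' bursts (per ROI and stimulus role, with latency, duration and amplitude in
#' baseline-SD units), narrowband phase couplings between ROI pairs with a
#' target phase-locking value, event-related potentials, background-noise
#' parameters and an epileptiform-spike rate.
#'
#' @slot bursts data.frame with columns roi, role, latency (s), duration (s),
#'   amplitude (baseline-SD units), f_lo, f_hi (Hz carrier band).
#' @slot couplings data.frame with columns roi_a, roi_b, f_lo, f_hi (Hz),
#'   plv (target in [0,1]), lag (rad), role, w_start, w_end (s relative to
#'   the role's stimulus onset), amplitude (uV).
#' @slot noise list with elements exponent (1/f slope) and rms (uV).
#' @slot erp data.frame with columns roi, amplitude (uV), latency (s),
#'   width (s).
#' @slot spikeRate epileptiform spikes per minute per channel.
#' @exportClass GroundTruth
setClass("GroundTruth", slots = c(
  bursts = "data.frame",
  couplings = "data.frame",
  noise = "list",
  erp = "data.frame",
  spikeRate = "numeric"
))

setValidity("GroundTruth", function(object) {
  msg <- character()
  if (nrow(object@couplings) &&
      (any(object@couplings$plv < 0) || any(object@couplings$plv > 1)))
    msg <- c(msg, "coupling target plv must lie in [0, 1]")
  if (nrow(object@bursts)) {
    if (any(object@bursts$latency < 0)) msg <- c(msg, "burst latencies must be >= 0")
    if (any(!is.finite(object@bursts$amplitude)))
      msg <- c(msg, "burst amplitudes must be finite")
  }
  if (object@spikeRate < 0) msg <- c(msg, "spikeRate must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a GroundTruth
#'
#' @param bursts data.frame of high-gamma bursts (see [GroundTruth-class]);
#'   build rows with [burstSpec()].
#' @param couplings data.frame of narrowband phase couplings; build rows with
#'   [couplingSpec()].
#' @param noise list(exponent=, rms=) for the 1/f background.
#' @param erp data.frame of per-ROI event-related potentials (roi, amplitude,
#'   latency, width).
#' @param spikeRate epileptiform spikes/minute per channel (default 0).
#' @return A [GroundTruth-class] object.
#' @export
groundTruth <- function(bursts = burstSpec()[0, ],
                        couplings = couplingSpec()[0, ],
                        noise = list(exponent = 1, rms = 20),
                        erp = data.frame(roi = character(), amplitude = numeric(),
                                         latency = numeric(), width = numeric()),
                        spikeRate = 0) {
  new("GroundTruth", bursts = bursts, couplings = couplings, noise = noise,
      erp = erp, spikeRate = spikeRate)
}

#' Describe one high-gamma burst or one phase coupling
#'
#' Row constructors for the [GroundTruth-class] tables.
#'
#' @param roi,role ROI label and stimulus role the burst is locked to.
#' @param latency burst-envelope peak latency after the role onset (s).
#' @param duration burst duration (s); the Gaussian amplitude envelope has
#'   SD = duration/2.
#' @param amplitude burst amplitude in baseline-SD units of the normalized
#'   high-gamma series (an amplitude of 3 targets a 300% peak).
#' @param band carrier band c(lo, hi) in Hz.
#' @return One-row data.frame.
#' @export
burstSpec <- function(roi = character(), role = character(), latency = numeric(),
                      duration = numeric(), amplitude = numeric(),
                      band = c(52, 120)) {
  n <- length(roi)
  data.frame(roi = roi, role = role, latency = latency, duration = duration,
             amplitude = amplitude,
             f_lo = rep(band[1], n), f_hi = rep(band[2], n))
}

#' @rdname burstSpec
#' @param roiA,roiB the coupled ROI pair.
#' @param plv target phase-locking value in [0, 1].
#' @param lag phase lag in radians of roiB relative to roiA.
#' @param window c(start, end) in seconds relative to the role onset.
#' @param couplingAmplitude amplitude (uV) of the injected narrowband
#'   component.
#' @export
couplingSpec <- function(roiA = character(), roiB = character(),
                         band = c(3, 7), plv = numeric(), lag = 0,
                         role = "N1", window = c(0.1, 0.9),
                         couplingAmplitude = 25) {
  n <- length(roiA)
  data.frame(roi_a = roiA, roi_b = roiB,
             f_lo = rep(band[1], n), f_hi = rep(band[2], n),
             plv = plv, lag = rep_len(lag, n), role = rep_len(role, n),
             w_start = rep(window[1], n), w_end = rep(window[2], n),
             amplitude = rep_len(couplingAmplitude, n))
}

## ---- continuous and epoched data ------------------------------------------

#' Recording: continuous multichannel iEEG signal
#'
#' Continuous signal with channel metadata and a per-sample rejection mask.
#' Masked samples (e.g. the 0.5 s windows around detected epileptic spikes)
#' keep their values; downstream averaging treats them as missing.
#'
#' @slot signal numeric matrix, time x channel, in microvolts.
#' @slot fs sampling rate in Hz.
#' @slot channels data.frame with one row per channel: name, subject, shank,
#'   contact (1 = deepest), roi (NA if unassigned), flags (comma-separated
#'   subset of soz, irritative, broken).
#' @slot mask logical matrix of the same shape as signal; TRUE = rejected.
#' @exportClass Recording
setClass("Recording", slots = c(
  signal = "matrix",
  fs = "numeric",
  channels = "data.frame",
  mask = "matrix"
))

setValidity("Recording", function(object) {
  msg <- character()
  if (object@fs <= 0) msg <- c(msg, "fs must be positive")
  if (nrow(object@channels) != ncol(object@signal))
    msg <- c(msg, "channels table must have one row per signal column")
  if (!identical(dim(object@mask), dim(object@signal)))
    msg <- c(msg, "mask shape must equal signal shape")
  if (any(is.na(object@signal[!object@mask])))
    msg <- c(msg, "NA signal values outside masked samples")
  if (length(msg)) msg else TRUE
})

#' Construct a Recording
#'
#' @param signal time x channel numeric matrix (uV).
#' @param fs sampling rate (Hz).
#' @param channels channel metadata data.frame; a `name` column is required,
#'   missing metadata columns are filled with NA.
#' @param mask optional logical matrix (TRUE = rejected sample); defaults to
#'   all-FALSE.
#' @return A [Recording-class] object.
#' @export
Recording <- function(signal, fs, channels, mask = NULL) {
  signal <- as.matrix(signal)
  if (is.null(mask)) mask <- matrix(FALSE, nrow(signal), ncol(signal))
  channels <- normalizeChannelTable(channels)
  new("Recording", signal = signal, fs = fs, channels = channels, mask = mask)
}

normalizeChannelTable <- function(channels) {
  channels <- as.data.frame(channels)
  if (is.null(channels$name)) stop("channel table needs a 'name' column")
  for (col in c("subject", "shank", "roi", "flags"))
    if (is.null(channels[[col]])) channels[[col]] <- NA_character_
  if (is.null(channels$contact)) channels$contact <- NA_integer_
  rownames(channels) <- NULL
  channels
}

#' SimulatedDataset: a synthetic session plus its ground truth
#'
#' @slot recording the simulated [Recording-class] (channel level).
#' @slot events the event table (one row per stimulus per trial).
#' @slot montage the channel-to-ROI map (subject, channel, roi).
#' @slot truth the [GroundTruth-class] that was injected.
#' @slot spikes data.frame (channel, time) of simulated epileptiform spikes.
#' @slot seed the integer seed the session was generated from.
#' @exportClass SimulatedDataset
setClass("SimulatedDataset", slots = c(
  recording = "Recording",
  events = "data.frame",
  montage = "data.frame",
  truth = "GroundTruth",
  spikes = "data.frame",
  seed = "integer"
))

setValidity("SimulatedDataset", function(object) {
  msg <- character()
  dur <- nrow(object@recording@signal) / object@recording@fs
  if (nrow(object@events) && (min(object@events$onset) < 0 ||
                              max(object@events$onset) > dur))
    msg <- c(msg, "every event onset must lie inside the recording")
  if (any(is.na(object@recording@channels$roi)))
    msg <- c(msg, "every simulated channel must carry an ROI label")
  if (length(msg)) msg else TRUE
})

#' TrialTensor: epoched signal with trial metadata
#'
#' The epoched data D(t, ch, tr): one extraction window per trial, anchored
#' at a reference stimulus onset (t = 0).
#'
#' @slot data numeric array time x channel x trial (uV).
#' @slot time numeric vector of sample times (s) relative to the anchor.
#' @slot fs sampling rate (Hz).
#' @slot channels channel metadata (as in [Recording-class]).
#' @slot trials data.frame of per-trial condition metadata.
#' @slot mask logical array, same shape as data.
#' @exportClass TrialTensor
setClass("TrialTensor", slots = c(
  data = "array",
  time = "numeric",
  fs = "numeric",
  channels = "data.frame",
  trials = "data.frame",
  mask = "array"
))

setValidity("TrialTensor", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 3L) msg <- c(msg, "data must be a 3-d array (time x channel x trial)")
  else {
    if (length(object@time) != d[1]) msg <- c(msg, "time axis length must match dim 1")
    if (nrow(object@channels) != d[2]) msg <- c(msg, "channel table must match dim 2")
    if (nrow(object@trials) != d[3]) msg <- c(msg, "trial metadata rows must match dim 3")
    if (!identical(dim(object@mask), d)) msg <- c(msg, "mask shape must equal data shape")
  }
  if (length(msg)) msg else TRUE
})

## ---- spectral and connectivity containers ---------------------------------

#' Spectrogram: multitaper time-frequency power
#'
#' Raw power is in dB (10*log10, reference 1 uV^2); after
#' [baselineNormalize()] values are per-(frequency, channel) z-scores of the
#' baseline distribution scaled to percent (baseline mean 0%, SD 100%).
#'
#' @slot values numeric array time x frequency x channel x trial.
#' @slot times window-center times (s); spacing is hop/fs.
#' @slot freqs frequency bin centers (Hz).
#' @slot channels,trials metadata carried from the [TrialTensor-class].
#' @slot baselineMu,baselineSigma frequency x channel baseline statistics
#'   (dB); empty until normalized.
#' @slot baselineWindow the baseline interval (s) used for normalization.
#' @slot normalized logical flag.
#' @slot hop hop size in samples of the underlying signal.
#' @slot fs signal sampling rate (Hz).
#' @exportClass Spectrogram
setClass("Spectrogram", slots = c(
  values = "array",
  times = "numeric",
  freqs = "numeric",
  channels = "data.frame",
  trials = "data.frame",
  baselineMu = "matrix",
  baselineSigma = "matrix",
  baselineWindow = "numeric",
  normalized = "logical",
  hop = "integer",
  fs = "numeric"
))

setValidity("Spectrogram", function(object) {
  msg <- character()
  d <- dim(object@values)
  if (length(d) != 4L) msg <- c(msg, "values must be time x frequency x channel x trial")
  else {
    if (length(object@times) != d[1]) msg <- c(msg, "times length must match dim 1")
    if (length(object@freqs) != d[2]) msg <- c(msg, "freqs length must match dim 2")
  }
  if (object@normalized && any(object@baselineSigma <= 0, na.rm = TRUE))
    msg <- c(msg, "baseline sigma must be positive for all retained bins")
  if (length(msg)) msg else TRUE
})

#' HGBSeries: high-gamma-band activity
#'
#' Band-mean of the normalized spectrogram over 52-120 Hz (excluding the
#' notched-out 100 Hz harmonic bins), in percent-of-baseline units.
#'
#' @slot perTrial numeric array time x channel x trial (%).
#' @slot trialAvg numeric matrix time x channel (%), the single-channel,
#'   trial-averaged series.
#' @slot times time axis (s), inherited from the spectrogram.
#' @slot channels,trials metadata.
#' @slot hop hop in samples; @slot fs sampling rate (Hz).
#' @slot band the averaged frequency interval (Hz).
#' @exportClass HGBSeries
setClass("HGBSeries", slots = c(
  perTrial = "array",
  trialAvg = "matrix",
  times = "numeric",
  channels = "data.frame",
  trials = "data.frame",
  hop = "integer",
  fs = "numeric",
  band = "numeric"
))

#' PLVSet: time-resolved phase-locking values
#'
#' Per within-subject channel pair and narrow frequency band, the across-trial
#' phase-locking value PLV(t) = |mean over trials of exp(i * dphi)|, evaluated
#' on the spectrogram hop grid. Raw values lie in [0, 1]; after
#' [normalizePlv()] values are percent-of-baseline z-scores.
#'
#' @slot plv numeric array time x band x pair.
#' @slot times time axis (s).
#' @slot bands data.frame (name, f_lo, f_hi).
#' @slot pairs data.frame (subject, chA, chB, roiA, roiB).
#' @slot normalized logical flag.
#' @slot nTrials number of trials the estimator used.
#' @slot baselineWindow baseline interval (s) once normalized.
#' @exportClass PLVSet
setClass("PLVSet", slots = c(
  plv = "array",
  times = "numeric",
  bands = "data.frame",
  pairs = "data.frame",
  normalized = "logical",
  nTrials = "integer",
  baselineWindow = "numeric"
))

setValidity("PLVSet", function(object) {
  msg <- character()
  d <- dim(object@plv)
  if (length(d) != 3L) msg <- c(msg, "plv must be time x band x pair")
  else {
    if (length(object@times) != d[1]) msg <- c(msg, "times length must match dim 1")
    if (nrow(object@bands) != d[2]) msg <- c(msg, "bands table must match dim 2")
    if (nrow(object@pairs) != d[3]) msg <- c(msg, "pairs table must match dim 3")
  }
  if (!object@normalized && length(object@plv) &&
      (min(object@plv, na.rm = TRUE) < -1e-9 || max(object@plv, na.rm = TRUE) > 1 + 1e-9))
    msg <- c(msg, "raw PLV must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
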