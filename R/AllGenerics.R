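# Generics, accessors and show methods.

#' @name accessors
#' @title Accessors for ieegnet containers
#' @description Slot access for the S4 containers: sampling rate, channel and
#'   trial metadata, time/frequency axes, signal matrix and rejection mask.
#' @param x an ieegnet object.
#' @return The corresponding slot value.
NULL

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("channelInfo", function(x) standardGeneric("channelInfo"))
#' @rdname accessors
#' @export
setGeneric("trialInfo", function(x) standardGeneric("trialInfo"))
#' @rdname accessors
#' @export
setGeneric("timeAxis", function(x) standardGeneric("timeAxis"))
#' @rdname accessors
#' @export
setGeneric("frequencyAxis", function(x) standardGeneric("frequencyAxis"))
#' @rdname accessors
#' @export
setGeneric("signalMatrix", function(x) standardGeneric("signalMatrix"))
#' @rdname accessors
#' @export
setGeneric("sampleMask", function(x) standardGeneric("sampleMask"))
#' @rdname accessors
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))
#' @rdname accessors
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))
#' @rdname accessors
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))
#' @rdname accessors
#' @export
setGeneric("truth", function(x) standardGeneric("truth"))
#' @rdname accessors
#' @export
setGeneric("trialAverage", function(x) standardGeneric("trialAverage"))
#' @rdname accessors
#' @export
setGeneric("plvPairs", function(x) standardGeneric("plvPairs"))
#' @rdname accessors
#' @export
setGeneric("plvBands", function(x) standardGeneric("plvBands"))

#' @rdname accessors
setMethod("samplingRate", "Recording", function(x) x@fs)
#' @rdname accessors
setMethod("samplingRate", "TrialTensor", function(x) x@fs)
#' @rdname accessors
setMethod("samplingRate", "Spectrogram", function(x) x@fs)
#' @rdname accessors
setMethod("samplingRate", "HGBSeries", function(x) x@fs)

#' @rdname accessors
setMethod("channelInfo", "Recording", function(x) x@channels)
#' @rdname accessors
setMethod("channelInfo", "TrialTensor", function(x) x@channels)
#' @rdname accessors
setMethod("channelInfo", "Spectrogram", function(x) x@channels)
#' @rdname accessors
setMethod("channelInfo", "HGBSeries", function(x) x@channels)

#' @rdname accessors
setMethod("trialInfo", "TrialTensor", function(x) x@trials)
#' @rdname accessors
setMethod("trialInfo", "Spectrogram", function(x) x@trials)
#' @rdname accessors
setMethod("trialInfo", "HGBSeries", function(x) x@trials)

#' @rdname accessors
setMethod("timeAxis", "TrialTensor", function(x) x@time)
#' @rdname accessors
setMethod("timeAxis", "Spectrogram", function(x) x@times)
#' @rdname accessors
setMethod("timeAxis", "HGBSeries", function(x) x@times)
#' @rdname accessors
setMethod("timeAxis", "PLVSet", function(x) x@times)

#' @rdname accessors
setMethod("frequencyAxis", "Spectrogram", function(x) x@freqs)

#' @rdname accessors
setMethod("signalMatrix", "Recording", function(x) x@signal)
#' @rdname accessors
setMethod("sampleMask", "Recording", function(x) x@mask)
#' @rdname accessors
setMethod("sampleMask", "TrialTensor", function(x) x@mask)

#' @rdname accessors
setMethod("isNormalized", "Spectrogram", function(x) x@normalized)
#' @rdname accessors
setMethod("isNormalized", "PLVSet", function(x) x@normalized)

#' @rdname accessors
setMethod("nChannels", "Recording", function(x) ncol(x@signal))
#' @rdname accessors
setMethod("nChannels", "TrialTensor", function(x) dim(x@data)[2])
#' @rdname accessors
setMethod("nTrials", "TrialTensor", function(x) dim(x@data)[3])
#' @rdname accessors
setMethod("nTrials", "Spectrogram", function(x) dim(x@values)[4])
#' @rdname accessors
setMethod("nTrials", "PLVSet", function(x) x@nTrials)

#' @rdname accessors
setMethod("truth", "SimulatedDataset", function(x) x@truth)
#' @rdname accessors
setMethod("trialAverage", "HGBSeries", function(x) x@trialAvg)
#' @rdname accessors
setMethod("plvPairs", "PLVSet", function(x) x@pairs)
#' @rdname accessors
setMethod("plvBands", "PLVSet", function(x) x@bands)

setMethod("show", "Recording", function(object) {
  cat(sprintf("Recording: %d channels x %d samples @ %g Hz (%.1f s)\n",
              ncol(object@signal), nrow(object@signal), object@fs,
              nrow(object@signal) / object@fs))
  nmask <- sum(object@mask)
  if (nmask) cat(sprintf("  masked samples: %d (%.2f%%)\n", nmask,
                         100 * nmask / length(object@mask)))
  rois <- unique(stats::na.omit(object@channels$roi))
  if (length(rois)) cat("  ROIs:", paste(rois, collapse = ", "), "\n")
})

setMethod("show", "TrialTensor", function(object) {
  d <- dim(object@data)
  cat(sprintf("TrialTensor: %d samples x %d channels x %d trials @ %g Hz\n",
              d[1], d[2], d[3], object@fs))
  cat(sprintf("  time window: [%g, %g] s\n", object@time[1],
              object@time[length(object@time)]))
})

setMethod("show", "Spectrogram", function(object) {
  d <- dim(object@values)
  cat(sprintf("Spectrogram%s: %d windows x %d bins x %d channels x %d trials\n",
              if (object@normalized) " (normalized, %-of-baseline)" else " (raw, dB)",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  time [%g, %g] s (hop %.5g ms), freq [%g, %g] Hz\n",
              min(object@times), max(object@times), 1000 * object@hop / object@fs,
              min(object@freqs), max(object@freqs)))
})

setMethod("show", "HGBSeries", function(object) {
  d <- dim(object@perTrial)
  cat(sprintf("HGBSeries (%g-%g Hz): %d windows x %d channels x %d trials\n",
              object@band[1], object@band[2], d[1], d[2], d[3]))
})

setMethod("show", "PLVSet", function(object) {
  d <- dim(object@plv)
  cat(sprintf("PLVSet%s: %d times x %d bands x %d pairs (N = %d trials)\n",
              if (object@normalized) " (normalized, %-of-baseline)" else " (raw)",
              d[1], d[2], d[3], object@nTrials))
})

setMethod("show", "SimulatedDataset", function(object) {
  cat(sprintf("SimulatedDataset (seed %d): %d trials, %d channels\n",
              object@seed, length(unique(object@events$trial)),
              ncol(object@recording@signal)))
  cat(sprintf("  truth: %d bursts, %d couplings, %d ERPs, spike rate %g/min\n",
              nrow(object@truth@bursts), nrow(object@truth@couplings),
              nrow(object@truth@erp), object@truth@spikeRate))
})

setMethod("show", "TaskSchedule", function(object) {
  cat(sprintf("TaskSchedule: %d trials, %g s stimuli, fixation U(%g, %g) s\n",
              object@nTrials, object@stimulusDuration,
              object@fixationRange[1], object@fixationRange[2]))
  cat("  roles:", paste(object@roles, collapse = " "), "\n")
})
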