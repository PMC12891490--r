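# Preprocessing chain: anti-alias downsampling, bipolar referencing,
# drift/notch filtering, channel exclusion and spike-window masking.
# Order follows the acquisition narrative: downsample -> bipolar ->
# high-pass -> notch -> spike masking.

#' Anti-alias low-pass and integer-factor downsampling
#'
#' Zero-phase Chebyshev type I low-pass (order 8, 0.05 dB passband ripple,
#' default cutoff 400 Hz) followed by integer-factor decimation. The
#' rejection mask is resampled by logical OR over each decimation group.
#'
#' @param rec a [Recording-class].
#' @param targetFs target sampling rate (Hz), default 512; must divide
#'   `samplingRate(rec)` to an integer factor.
#' @param cutoffHz anti-alias cutoff (Hz).
#' @return the downsampled [Recording-class].
#' @export
antialiasDownsample <- function(rec, targetFs = 512, cutoffHz = 400) {
  stopifnot(is(rec, "Recording"))
  if (rec@fs < targetFs) stop("target rate exceeds the recording rate")
  factor <- rec@fs / targetFs
  if (abs(factor - round(factor)) > 1e-9)
    stop("non-integer decimation factor ", format(factor),
         "; fractional resampling is not supported")
  factor <- as.integer(round(factor))
  if (factor == 1L) return(rec)
  filt <- designAntialias(min(cutoffHz, 0.999 * rec@fs / 2), rec@fs)
  sig <- zeroPhase(filt, rec@signal)
  keep <- seq(1L, nrow(sig), by = factor)
  newMask <- matrix(FALSE, length(keep), ncol(sig))
  for (g in seq_len(factor)) {
    idx <- keep + (g - 1L)
    ok <- idx <= nrow(rec@mask)
    newMask[ok, ] <- newMask[ok, ] | rec@mask[idx[ok], , drop = FALSE]
  }
  new("Recording", signal = sig[keep, , drop = FALSE], fs = targetFs,
      channels = rec@channels, mask = newMask)
}

#' Bipolar referencing along each electrode shank
#'
#' Derives bipolar channels by subtracting each contact from its closest
#' neighbour on the same shank, starting from the deepest contact
#' (contact index 1): the k-th bipolar channel is contact_k - contact_(k+1),
#' named "A1-A2" style. A shank with n contacts yields n - 1 channels;
#' single-contact shanks are dropped with a warning. The mask is the OR of
#' the two parent contacts, flags are their union, and the ROI is the
#' deeper contact's ROI if assigned, else the neighbour's (at least one of
#' the two contacts must lie in the ROI).
#'
#' @param rec a contact-level [Recording-class]; the channel table must
#'   carry shank and contact columns.
#' @return a channel-level (bipolar) [Recording-class].
#' @export
bipolarReference <- function(rec) {
  stopifnot(is(rec, "Recording"))
  ch <- rec@channels
  if (any(is.na(ch$shank)) || any(is.na(ch$contact)))
    stop("bipolar referencing needs shank and contact metadata")
  key <- paste(ch$subject, ch$shank, sep = "\r")
  sigCols <- list(); maskCols <- list(); rows <- list()
  for (sh in unique(key)) {
    idx <- which(key == sh)
    idx <- idx[order(ch$contact[idx])]
    if (length(idx) < 2L) {
      warning("shank ", ch$shank[idx[1]], " has a single contact; dropped")
      next
    }
    for (k in seq_len(length(idx) - 1L)) {
      i <- idx[k]; j <- idx[k + 1L]
      sigCols[[length(sigCols) + 1L]] <- rec@signal[, i] - rec@signal[, j]
      maskCols[[length(maskCols) + 1L]] <- rec@mask[, i] | rec@mask[, j]
      fl <- union(splitFlags(ch$flags[i]), splitFlags(ch$flags[j]))
      rows[[length(rows) + 1L]] <- data.frame(
        name = paste0(ch$name[i], "-", ch$name[j]),
        subject = ch$subject[i], shank = ch$shank[i],
        contact = ch$contact[i],
        roi = if (!is.na(ch$roi[i])) ch$roi[i] else ch$roi[j],
        flags = if (length(fl)) paste(fl, collapse = ",") else NA_character_)
    }
  }
  if (!length(sigCols)) stop("no shank with at least two contacts")
  new("Recording", signal = do.call(cbind, sigCols), fs = rec@fs,
      channels = do.call(rbind, rows), mask = do.call(cbind, maskCols))
}

splitFlags <- function(x) {
  if (is.na(x) || !nzchar(x)) character() else strsplit(x, ",", fixed = TRUE)[[1]]
}

#' Drift and line-noise filtering
#'
#' Removes the channel mean, high-pass filters at 0.1 Hz (Butterworth,
#' 6th order, realized as cascaded second-order sections) and band-stop
#' filters the line frequency and its harmonics (48-52, 98-102, 148-152 Hz;
#' Butterworth, 6th order). All filters are zero-phase (forward-backward).
#' Notch bands at or above the Nyquist frequency are skipped.
#'
#' @param rec a [Recording-class].
#' @param hpHz high-pass cutoff (Hz).
#' @param notchHz center frequencies of the band-stop filters (Hz).
#' @param notchHalfWidth half-width of each stop band (Hz).
#' @return the filtered [Recording-class].
#' @export
filterChain <- function(rec, hpHz = 0.1, notchHz = c(50, 100, 150),
                        notchHalfWidth = 2) {
  stopifnot(is(rec, "Recording"))
  sig <- sweep(rec@signal, 2, colMeans(rec@signal))
  hp <- butterHighpassSOS(6L, hpHz, rec@fs)
  sig <- zeroPhase(hp, sig)
  for (f0 in notchHz) {
    if (f0 + notchHalfWidth >= rec@fs / 2) next
    bs <- designBandstop(c(f0 - notchHalfWidth, f0 + notchHalfWidth), rec@fs)
    sig <- zeroPhase(bs, sig)
  }
  new("Recording", signal = sig, fs = rec@fs, channels = rec@channels,
      mask = rec@mask)
}

#' Mask the windows around detected epileptic spikes
#'
#' Sets the rejection mask to TRUE in the closed window [t - half, t + half]
#' around each spike on the affected channel. Signal values are untouched:
#' masking, not zeroing; masked samples propagate as missing values into all
#' downstream averages.
#'
#' @param rec a [Recording-class].
#' @param spikes data.frame with columns channel, time (s).
#' @param halfWidth half of the rejection window (s); default 0.25 for the
#'   0.5-s window centered on the spike.
#' @return the [Recording-class] with an updated mask.
#' @export
applySpikeMask <- function(rec, spikes, halfWidth = 0.25) {
  stopifnot(is(rec, "Recording"))
  spikes <- as.data.frame(spikes)
  if (!nrow(spikes)) return(rec)
  mask <- rec@mask
  n <- nrow(rec@signal)
  for (r in seq_len(nrow(spikes))) {
    j <- match(spikes$channel[r], rec@channels$name)
    if (is.na(j)) stop("unknown channel in spike table: ", spikes$channel[r])
    t0 <- spikes$time[r]
    i1 <- max(1L, ceiling((t0 - halfWidth) * rec@fs - 1e-9) + 1L)
    i2 <- min(n, floor((t0 + halfWidth) * rec@fs + 1e-9) + 1L)
    if (i2 >= i1) mask[i1:i2, j] <- TRUE
  }
  new("Recording", signal = rec@signal, fs = rec@fs,
      channels = rec@channels, mask = mask)
}

#' Reject flagged channels
#'
#' Removes channels carrying any of the given flags (seizure-onset zone,
#' irritative zone, broken).
#'
#' @param rec a [Recording-class].
#' @param dropFlags character subset of c("soz", "irritative", "broken").
#' @return the [Recording-class] without the flagged channels.
#' @export
rejectChannels <- function(rec, dropFlags = c("soz", "irritative", "broken")) {
  stopifnot(is(rec, "Recording"))
  stopifnot(all(dropFlags %in% c("soz", "irritative", "broken")))
  bad <- vapply(rec@channels$flags,
                function(f) length(intersect(splitFlags(f), dropFlags)) > 0,
                logical(1))
  if (all(bad)) stop("all channels would be removed")
  if (!any(bad)) return(rec)
  message(sum(bad), " of ", length(bad), " channels rejected (",
          paste(dropFlags, collapse = ", "), ")")
  keep <- which(!bad)
  new("Recording", signal = rec@signal[, keep, drop = FALSE], fs = rec@fs,
      channels = rec@channels[keep, , drop = FALSE],
      mask = rec@mask[, keep, drop = FALSE])
}

#' Heuristic amplitude-threshold spike detector (convenience only)
#'
#' Flags samples whose 20-80 Hz envelope exceeds a robust z threshold. This
#' is a simple convenience heuristic, not a validated clinical detector;
#' curated spike annotations should be preferred and consumed via
#' [applySpikeMask()].
#'
#' @param rec a [Recording-class].
#' @param zThreshold envelope z-score threshold (default 6).
#' @param minSeparation minimum separation between reported events (s).
#' @return data.frame (channel, time) suitable for [applySpikeMask()].
#' @export
detectSpikes <- function(rec, zThreshold = 6, minSeparation = 0.25) {
  stopifnot(is(rec, "Recording"))
  bp <- designBandpass(c(20, 80), rec@fs)
  out <- list()
  for (j in seq_len(ncol(rec@signal))) {
    env <- Mod(analyticSignal(zeroPhase(bp, rec@signal[, j])))
    z <- (env - median(env)) / (stats::mad(env) + 1e-12)
    hits <- which(z > zThreshold)
    if (!length(hits)) next
    tt <- (hits - 1L) / rec@fs
    keepT <- tt[c(TRUE, diff(tt) > minSeparation)]
    out[[length(out) + 1L]] <- data.frame(channel = rec@channels$name[j],
                                          time = keepT)
  }
  if (!length(out)) return(data.frame(channel = character(), time = numeric()))
  do.call(rbind, out)
}
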