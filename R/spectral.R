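# Multitaper time-frequency decomposition and baseline z-score
# normalization to percent-of-baseline units.

# Slepian (DPSS) tapers from the symmetric tridiagonal eigenproblem:
# diagonal ((N-1-2t)/2)^2 cos(2*pi*W), off-diagonal t(N-t)/2. Tapers are
# normalized to unit energy; results are cached per (n, nw, k).
tapersCache <- new.env(parent = emptyenv())

slepianTapers <- function(n, nw = 1.5, k = 2L) {
  key <- paste(n, nw, k, sep = "_")
  if (!is.null(tapersCache[[key]])) return(tapersCache[[key]])
  W <- nw / n
  t0 <- 0:(n - 1)
  dg <- ((n - 1 - 2 * t0) / 2)^2 * cos(2 * pi * W)
  od <- seq_len(n - 1) * (n - seq_len(n - 1)) / 2
  M <- diag(dg)
  M[cbind(seq_len(n - 1), 2:n)] <- od
  M[cbind(2:n, seq_len(n - 1))] <- od
  v <- eigen(M, symmetric = TRUE)$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    v[, j] <- v[, j] / sqrt(sum(v[, j]^2))
    if (j %% 2 == 1 && sum(v[, j]) < 0) v[, j] <- -v[, j]
  }
  tapersCache[[key]] <- v
  v
}

# Window-center time stamps of the sliding analysis, given a trial time axis.
windowCenters <- function(time, wlen, hop) {
  nt <- length(time)
  if (wlen > nt) stop("analysis window longer than the trial")
  starts <- seq(1L, nt - wlen + 1L, by = hop)
  (time[starts] + time[starts + wlen - 1L]) / 2
}

#' Multitaper time-frequency decomposition
#'
#' Sliding-window multitaper power spectral density: per window, the mean
#' over K Slepian-taper periodograms, converted to dB (10*log10, reference
#' 1 uV^2). Defaults follow the pipeline conventions: 0.5-s windows, two
#' tapers (time-bandwidth product NW = 1.5, so K = 2NW - 1), a 16-sample
#' hop (31.25 ms at 512 Hz) and a 0-120 Hz grid with 2 Hz bins (the natural
#' resolution of the 0.5-s window). Windows overlapping the trial edges are
#' dropped; windows containing masked samples are flagged missing (NA) for
#' that channel and trial.
#'
#' @param trials a [TrialTensor-class].
#' @param winS analysis window length (s).
#' @param hopSamples hop between window starts (samples).
#' @param nTapers number of Slepian tapers.
#' @param nw time-bandwidth product.
#' @param fmax maximum frequency retained (Hz).
#' @param dfHz frequency bin spacing (Hz); the FFT length is chosen to align
#'   the bin grid with this spacing.
#' @return a raw (dB) [Spectrogram-class].
#' @export
multitaperSpectrogram <- function(trials, winS = 0.5, hopSamples = 16L,
                                  nTapers = 2L, nw = 1.5, fmax = 120,
                                  dfHz = 2) {
  stopifnot(is(trials, "TrialTensor"))
  fs <- trials@fs
  wlen <- round(winS * fs)
  d <- dim(trials@data)
  nt <- d[1]
  if (wlen > nt) stop("analysis window longer than the trial")
  starts <- seq(1L, nt - wlen + 1L, by = hopSamples)
  nWin <- length(starts)
  nfft <- max(wlen, round(fs / dfHz))
  freqsAll <- (0:(nfft %/% 2)) * fs / nfft
  fIdx <- which(freqsAll <= fmax + 1e-9)
  freqs <- freqsAll[fIdx]
  tapers <- slepianTapers(wlen, nw, nTapers)
  segIdx <- outer(0:(wlen - 1L), starts, "+")   # wlen x nWin
  vals <- array(NA_real_, c(nWin, length(freqs), d[2], d[3]))
  anyMask <- any(trials@mask)
  for (tr in seq_len(d[3])) {
    for (ch in seq_len(d[2])) {
      x <- trials@data[, ch, tr]
      seg <- matrix(x[segIdx], wlen, nWin)
      p <- 0
      for (k in seq_len(nTapers)) {
        tp <- seg * tapers[, k]
        if (nfft > wlen) tp <- rbind(tp, matrix(0, nfft - wlen, nWin))
        Fk <- stats::mvfft(tp)
        p <- p + Mod(Fk[fIdx, , drop = FALSE])^2
      }
      p <- p / (nTapers * fs)
      pdb <- 10 * log10(pmax(p, 1e-300))
      if (anyMask) {
        m <- trials@mask[, ch, tr]
        bad <- colSums(matrix(m[segIdx], wlen, nWin)) > 0
        pdb[, bad] <- NA_real_
      }
      vals[, , ch, tr] <- t(pdb)
    }
  }
  times <- (trials@time[starts] + trials@time[starts + wlen - 1L]) / 2
  new("Spectrogram", values = vals, times = times, freqs = freqs,
      channels = trials@channels, trials = trials@trials,
      baselineMu = matrix(numeric(0), 0, 0),
      baselineSigma = matrix(numeric(0), 0, 0),
      baselineWindow = numeric(0), normalized = FALSE,
      hop = as.integer(hopSamples), fs = fs)
}

#' Baseline z-score normalization to percent-of-baseline units
#'
#' For each frequency bin and channel, the raw dB power is z-scored against
#' the mean and SD computed from all baseline time points of all trials,
#' then scaled by 100: the mean baseline activity is 0% and mean +- SD is
#' +- 100%. This corrects the 1/f decay of the iEEG spectrum and puts all
#' bins and channels on a common scale.
#'
#' @param spec a raw (dB) [Spectrogram-class].
#' @param baseline c(start, end) s of the baseline (fixation) interval;
#'   default [-1, -0.25].
#' @return the normalized [Spectrogram-class] (values in %).
#' @export
baselineNormalize <- function(spec, baseline = c(-1, -0.25)) {
  stopifnot(is(spec, "Spectrogram"))
  if (spec@normalized) stop("spectrogram is already normalized")
  bIdx <- which(spec@times >= baseline[1] - 1e-9 &
                  spec@times <= baseline[2] + 1e-9)
  if (!length(bIdx)) stop("no analysis windows inside the baseline interval")
  d <- dim(spec@values)
  mu <- matrix(NA_real_, d[2], d[3])
  sg <- matrix(NA_real_, d[2], d[3])
  vals <- spec@values
  for (ch in seq_len(d[3])) {
    # baseline samples of all trials: (time x trial) rows, freq columns
    base <- matrix(aperm(spec@values[bIdx, , ch, , drop = FALSE],
                         c(1, 4, 2, 3)), ncol = d[2])
    mu[, ch] <- colMeans(base, na.rm = TRUE)
    sg[, ch] <- apply(base, 2, sd, na.rm = TRUE)
    bad <- which(!is.na(sg[, ch]) & sg[, ch] <= 1e-7)
    if (length(bad))
      stop("degenerate baseline (sigma = 0) in channel ",
           spec@channels$name[ch], " at ", spec@freqs[bad[1]], " Hz")
    vals[, , ch, ] <- 100 *
      sweep(sweep(spec@values[, , ch, , drop = FALSE], 2, mu[, ch]),
            2, sg[, ch], "/")
  }
  new("Spectrogram", values = vals, times = spec@times, freqs = spec@freqs,
      channels = spec@channels, trials = spec@trials, baselineMu = mu,
      baselineSigma = sg, baselineWindow = baseline, normalized = TRUE,
      hop = spec@hop, fs = spec@fs)
}

#' ROI-average spectrogram
#'
#' Grand average for one region of interest: trial-average each channel
#' first, then average across all channels of all subjects assigned to the
#' ROI. Missing values (masked windows) are excluded pairwise.
#'
#' @param spec a normalized [Spectrogram-class].
#' @param map channel map data.frame (subject, channel, roi) assigning
#'   channels to ROIs; defaults to the roi column of the channel table.
#' @param roi the ROI label.
#' @return time x frequency matrix with attributes nChannels and nSubjects.
#' @export
roiSpectrogram <- function(spec, map = NULL, roi) {
  stopifnot(is(spec, "Spectrogram"))
  chIdx <- roiChannelIndices(spec@channels, map, roi)
  d <- dim(spec@values)
  acc <- array(NA_real_, c(d[1], d[2], length(chIdx)))
  for (k in seq_along(chIdx))
    acc[, , k] <- apply(spec@values[, , chIdx[k], , drop = FALSE],
                        c(1, 2), mean, na.rm = TRUE)
  out <- apply(acc, c(1, 2), mean, na.rm = TRUE)
  dimnames(out) <- NULL
  subj <- spec@channels$subject[chIdx]
  attr(out, "nChannels") <- length(chIdx)
  attr(out, "nSubjects") <- length(unique(subj[!is.na(subj)]))
  attr(out, "times") <- spec@times
  attr(out, "freqs") <- spec@freqs
  out
}

# Channel indices of an ROI, from a channel map or the channel table itself.
roiChannelIndices <- function(channels, map, roi) {
  if (is.null(map)) {
    idx <- which(channels$roi == roi)
  } else {
    map <- as.data.frame(map)
    keyCh <- paste(channels$subject, channels$name, sep = "\r")
    keyMap <- paste(map$subject, map$channel, sep = "\r")
    idx <- which(keyCh %in% keyMap[map$roi == roi])
  }
  if (!length(idx)) stop("no channels assigned to ROI ", roi)
  idx
}
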