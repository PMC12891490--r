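# Shared fixture builders: everything is generated in code at test time.

# Contact-level recording: two shanks (A: 8 contacts, B: 10 contacts) with
# optional common-mode and per-contact signals.
contactRecording <- function(n = 1024L, fs = 512, seed = 1L,
                             common = NULL, flags = NULL) {
  set.seed(seed)
  nA <- 8L; nB <- 10L
  chans <- data.frame(
    name = c(paste0("A", 1:nA), paste0("B", 1:nB)),
    subject = "s01",
    shank = c(rep("A", nA), rep("B", nB)),
    contact = c(1:nA, 1:nB),
    roi = c(rep("IPS", nA), rep("MOG", nB)),
    flags = NA_character_)
  if (!is.null(flags)) chans$flags[seq_along(flags)] <- flags
  sig <- matrix(rnorm(n * (nA + nB)), n)
  if (!is.null(common)) sig <- sig + common
  Recording(sig, fs, chans)
}

# Minimal montage: one or more channels per ROI, single subject by default.
tinyMontage <- function(rois = c("IPS", "MOG"), nPerRoi = 1L,
                        subject = "s01") {
  data.frame(subject = subject,
             channel = paste0(rep(rois, each = nPerRoi), "_",
                              seq_len(nPerRoi)),
             roi = rep(rois, each = nPerRoi))
}

# Small simulated session for recovery tests.
quickSim <- function(nTrials = 20L, rois = c("IPS", "MOG"),
                     bursts = NULL, couplings = couplingSpec()[0, ],
                     seed = 1L, nPerRoi = 1L, spikeRate = 0) {
  if (is.null(bursts))
    bursts <- burstSpec(roi = rois[1], role = "N1", latency = 0.2,
                        duration = 0.3, amplitude = 3)
  gt <- groundTruth(bursts = bursts, couplings = couplings,
                    spikeRate = spikeRate)
  simulateSubject(taskSchedule(nTrials = nTrials), gt,
                  tinyMontage(rois, nPerRoi), seed = seed)
}

# Hand-built normalized-spectrogram container (values in %).
makeSpec <- function(vals, times, freqs, normalized = TRUE, fs = 512,
                     hop = 16L, subjects = NULL) {
  d <- dim(vals)
  chans <- data.frame(name = paste0("ch", seq_len(d[3])),
                      subject = if (is.null(subjects)) "s01" else subjects,
                      shank = NA_character_, contact = NA_integer_,
                      roi = NA_character_, flags = NA_character_)
  new("Spectrogram", values = vals, times = times, freqs = freqs,
      channels = chans, trials = data.frame(trial = seq_len(d[4])),
      baselineMu = matrix(1, d[2], d[3]),
      baselineSigma = matrix(1, d[2], d[3]),
      baselineWindow = c(-1, -0.25), normalized = normalized,
      hop = hop, fs = fs)
}

# Hand-built HGB container from a per-trial array, with role onsets.
makeHgb <- function(perTrial, times, rois = NULL, fs = 512, hop = 16L,
                    trials = NULL, roleOnsets = c(N1 = 0, O1 = 1.05,
                                                  N2 = 2.1, O2 = 3.15,
                                                  N3 = 4.2)) {
  d <- dim(perTrial)
  chans <- data.frame(name = paste0("ch", seq_len(d[2])),
                      subject = "s01", shank = NA_character_,
                      contact = NA_integer_,
                      roi = if (is.null(rois)) "IPS" else rois,
                      flags = NA_character_)
  if (is.null(trials)) trials <- data.frame(trial = seq_len(d[3]))
  attr(trials, "roleOnsets") <- roleOnsets
  trialAvg <- apply(perTrial, c(1, 2), mean, na.rm = TRUE)
  new("HGBSeries", perTrial = perTrial, trialAvg = trialAvg, times = times,
      channels = chans, trials = trials, hop = as.integer(hop), fs = fs,
      band = c(52, 120))
}

# Epoched fixture for phase/PLV tests: each channel x trial trace is g(t).
signalTensorPlv <- function(g, fs = 512, nCh = 1L, nTr = 1L,
                            window = c(-1, 2)) {
  n <- round(diff(window) * fs) + 1L
  tvec <- window[1] + (0:(n - 1)) / fs
  dat <- array(0, c(n, nCh, nTr))
  for (ch in seq_len(nCh)) for (tr in seq_len(nTr)) dat[, ch, tr] <- g(tvec)
  trials <- data.frame(trial = seq_len(nTr), correct = TRUE)
  attr(trials, "roleOnsets") <- c(N1 = 0)
  new("TrialTensor", data = dat, time = tvec, fs = fs,
      channels = data.frame(name = paste0("ch", seq_len(nCh)),
                            subject = "s01", shank = NA_character_,
                            contact = NA_integer_, roi = NA_character_,
                            flags = NA_character_),
      trials = trials, mask = array(FALSE, dim(dat)))
}

unwrapPhase <- function(ph) {
  d <- diff(ph)
  d <- d - 2 * pi * round(d / (2 * pi))
  cumsum(c(ph[1], d))
}
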