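# Synthetic task-locked iEEG sessions with known ground truth.
#
# The generator emulates the sequential arithmetic task: per trial a jittered
# fixation cross is followed by seven 1.05-s stimuli (N1 O1 N2 O2 N3 EQ
# RESULT), a response and feedback. On top of a 1/f background it injects
# per-ROI high-gamma bursts (Gaussian-envelope amplitude modulation of
# band-limited noise), low-frequency event-related potentials, narrowband
# phase couplings of known strength, and optional epileptiform spikes.

#' Generate the event table of a simulated session
#'
#' One row per stimulus per trial. Within a trial the stimulus onsets are
#' spaced exactly by the stimulus duration; trials are separated by the
#' jittered fixation and a feedback padding. Per-trial condition metadata
#' (format, difficulty, operator signs, decade crossing, correctness,
#' reaction time) is repeated on each of the trial's rows.
#'
#' @param schedule a [TaskSchedule-class].
#' @param seed integer seed; fixed seed gives an identical table.
#' @return data.frame with columns trial, role, onset (s), format,
#'   difficulty, op1, op2, decade_role, response, correct, rt (s).
#' @examples
#' ev <- generateEvents(taskSchedule(nTrials = 10), seed = 1)
#' nrow(ev)  # 70 = 10 trials x 7 roles
#' @export
generateEvents <- function(schedule, seed = 1L) {
  stopifnot(is(schedule, "TaskSchedule"))
  if (schedule@stimulusDuration <= 0) stop("invalid schedule: non-positive durations")
  set.seed(seed)
  nTr <- schedule@nTrials
  roles <- schedule@roles
  sd1 <- schedule@stimulusDuration
  rows <- vector("list", nTr)
  cursor <- 0
  for (tr in seq_len(nTr)) {
    fix <- runif(1, schedule@fixationRange[1], schedule@fixationRange[2])
    onsets <- cursor + fix + (seq_along(roles) - 1L) * sd1
    rt <- min(5, max(0.2, rnorm(1, schedule@rtMean, schedule@rtSd)))
    correct <- rbinom(1, 1, schedule@correctRate) == 1
    fmt <- sample(schedule@formats, 1)
    decRole <- if (identical(schedule@difficulty, "difficult"))
      sample(c("N2", "N3"), 1) else NA_character_
    rows[[tr]] <- data.frame(
      trial = tr, role = roles, onset = onsets, format = fmt,
      difficulty = schedule@difficulty,
      op1 = sample(c("+", "-"), 1), op2 = sample(c("+", "-"), 1),
      decade_role = decRole,
      response = if (correct) "yes" else "no", correct = correct, rt = rt)
    cursor <- onsets[length(onsets)] + sd1 + rt + schedule@feedbackDuration
  }
  ev <- do.call(rbind, rows)
  rownames(ev) <- NULL
  ev
}

#' Generate 1/f ("pink") background noise
#'
#' Spectral shaping of Gaussian white noise in the frequency domain: the
#' amplitude spectrum is scaled by f^(-exponent/2) (DC removed), then the
#' series is rescaled to the requested RMS exactly.
#'
#' @param n number of samples (>= 2).
#' @param exponent spectral exponent of the 1/f^exponent power decay
#'   (0 = white).
#' @param rms root-mean-square amplitude of the output.
#' @param seed optional integer seed.
#' @return numeric vector of length n.
#' @export
makePinkNoise <- function(n, exponent = 1, rms = 1, seed = NULL) {
  stopifnot(n >= 2)
  if (!is.null(seed)) set.seed(seed)
  # shape the spectrum at a highly composite length (mixed-radix FFT stays
  # O(n log n)), then truncate
  nf <- stats::nextn(n, c(2, 3, 5))
  w <- rnorm(nf)
  W <- stats::fft(w)
  k <- seq_len(nf) - 1L
  f <- pmin(k, nf - k)           # symmetric bin index; f[1] is DC
  sc <- c(0, f[-1]^(-exponent / 2))
  x <- Re(stats::fft(W * sc, inverse = TRUE))[seq_len(n)] / nf
  x <- x - mean(x)
  x * rms / sqrt(mean(x^2))
}

# Mean resultant length of a von Mises distribution: A(kappa) = I1/I0.
vonMisesResultant <- function(kappa) {
  besselI(kappa, 1, expon.scaled = TRUE) / besselI(kappa, 0, expon.scaled = TRUE)
}

# Concentration kappa with A(kappa) = r.
kappaFromPlv <- function(r) {
  stopifnot(r >= 0, r <= 1)
  if (r < 1e-9) return(0)
  if (r > 1 - 1e-5) return(Inf)
  stats::uniroot(function(k) vonMisesResultant(k) - r,
                 interval = c(1e-8, 5000), tol = 1e-10)$root
}

# Best & Fisher (1979) rejection sampler for the von Mises distribution
# centred at 0. kappa = 0 falls back to uniform, kappa = Inf to a point mass.
rVonMises <- function(n, kappa) {
  if (kappa == 0) return(runif(n, -pi, pi))
  if (!is.finite(kappa)) return(rep(0, n))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      out[i] <- sign(u[3] - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  out
}

#' Inject a narrowband phase coupling of known strength into two signals
#'
#' Adds, inside each given window, a shared narrowband (single-carrier)
#' component whose per-window phase difference is lag + delta, with delta
#' drawn from a von Mises distribution whose concentration kappa solves
#' I1(kappa)/I0(kappa) = targetPlv. targetPlv = 1 gives a constant phase
#' difference (kappa = Inf), targetPlv = 0 a uniform one.
#'
#' @param xA,xB the two signals (numeric vectors of equal length).
#' @param fs sampling rate (Hz).
#' @param band c(lo, hi) Hz; the carrier frequency is the band center.
#' @param targetPlv target phase-locking value in [0, 1].
#' @param lag mean phase lag (radians) of xB relative to xA.
#' @param windows matrix or data.frame with columns start, end (s), one row
#'   per window (one phase draw per window, i.e. per trial).
#' @param amplitude amplitude (uV) of the injected component.
#' @param seed optional integer seed.
#' @return list with elements a, b (the modified signals) and phaseDiff (the
#'   per-window injected phase differences, radians).
#' @export
injectPhaseCoupling <- function(xA, xB, fs, band, targetPlv, lag = 0,
                                windows, amplitude = 1, seed = NULL) {
  if (targetPlv < 0 || targetPlv > 1) stop("targetPlv must lie in [0, 1]")
  if (max(band) >= fs / 2) stop("coupling band lies outside the Nyquist range")
  if (!is.null(seed)) set.seed(seed)
  windows <- as.matrix(windows)
  kap <- kappaFromPlv(targetPlv)
  delta <- rVonMises(nrow(windows), kap)
  f0 <- mean(band)
  n <- length(xA)
  tvec <- (seq_len(n) - 1L) / fs
  for (w in seq_len(nrow(windows))) {
    i1 <- max(1L, floor(windows[w, 1] * fs) + 1L)
    i2 <- min(n, ceiling(windows[w, 2] * fs) + 1L)
    if (i2 <= i1) next
    idx <- i1:i2
    env <- 0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = length(idx))))
    ph <- 2 * pi * f0 * tvec[idx] + runif(1, 0, 2 * pi)
    xA[idx] <- xA[idx] + amplitude * env * cos(ph)
    xB[idx] <- xB[idx] + amplitude * env * cos(ph + lag + delta[w])
  }
  list(a = xA, b = xB, phaseDiff = lag + delta)
}

# Per-bin baseline SD (dB) of a K-taper log-power estimate: each taper
# periodogram has 2 dof, the K-taper mean 2K, and var(log chi2_2K/2K) =
# trigamma(K).
binBaselineSdDb <- function(nTapers = 2L) {
  (10 / log(10)) * sqrt(trigamma(nTapers))
}

# Window-averaged power of a unit Gaussian amplitude envelope (SD sigma)
# over a centred analysis window of length winS.
envelopeWindowFactor <- function(sigma, winS = 0.5) {
  u <- seq(-winS / 2, winS / 2, length.out = 201L)
  mean(exp(-u^2 / sigma^2))
}

#' Simulate one subject's task session
#'
#' Builds a channel-level (referenced) continuous recording: 1/f background
#' plus, per ground-truth entry, event-locked high-gamma bursts,
#' event-related potentials, narrowband phase couplings and epileptiform
#' spikes. Burst amplitudes are specified in baseline-SD units of the
#' normalized high-gamma series; the injected power is calibrated
#' analytically from the K-taper log-power statistics (see the methods
#' vignette).
#'
#' @param schedule a [TaskSchedule-class].
#' @param truth a [GroundTruth-class].
#' @param montage data.frame with columns subject, channel, roi (one row per
#'   channel).
#' @param fs sampling rate in Hz (default 512, the post-downsampling rate;
#'   use 2048 to exercise the downsampler).
#' @param seed integer seed; full determinism under a fixed seed.
#' @return a [SimulatedDataset-class].
#' @export
simulateSubject <- function(schedule, truth, montage, fs = 512, seed = 1L) {
  stopifnot(is(schedule, "TaskSchedule"), is(truth, "GroundTruth"))
  if (fs < 256) stop("fs must be >= 256 Hz")
  montage <- as.data.frame(montage)
  if (!nrow(montage)) stop("montage must be non-empty")
  rois <- unique(montage$roi)
  badRoi <- setdiff(unique(c(truth@couplings$roi_a, truth@couplings$roi_b)), rois)
  if (length(badRoi))
    stop("configuration error: coupling references ROI(s) absent from montage: ",
         paste(badRoi, collapse = ", "))

  events <- generateEvents(schedule, seed = seed)
  leadIn <- 2.5
  events$onset <- events$onset + leadIn
  dur <- max(events$onset) + schedule@feedbackDuration + 9.5
  n <- ceiling(dur * fs)
  nCh <- nrow(montage)

  set.seed(seed + 1L)
  sig <- matrix(0, n, nCh)
  for (j in seq_len(nCh))
    sig[, j] <- makePinkNoise(n, truth@noise$exponent, truth@noise$rms)

  tvec <- (seq_len(n) - 1L) / fs

  # event-related potentials: damped half-sine, one per stimulus onset
  if (nrow(truth@erp)) {
    stimOnsets <- events$onset[events$role != "RESULT"]
    for (r in seq_len(nrow(truth@erp))) {
      e <- truth@erp[r, ]
      chs <- which(montage$roi == e$roi)
      if (!length(chs)) next
      nw <- round(e$width * fs)
      wshape <- e$amplitude * sin(pi * seq(0, 1, length.out = nw)) *
        exp(-2 * seq(0, 1, length.out = nw))
      for (on in stimOnsets) {
        i1 <- round((on + e$latency) * fs) + 1L
        idx <- i1:(i1 + nw - 1L)
        keep <- idx >= 1L & idx <= n
        sig[idx[keep], chs] <- sig[idx[keep], chs] + wshape[keep]
      }
    }
  }

  # high-gamma bursts: Gaussian-envelope modulation of band-limited noise
  if (nrow(truth@bursts)) {
    sigmaDb <- binBaselineSdDb(2L)
    for (r in seq_len(nrow(truth@bursts))) {
      b <- truth@bursts[r, ]
      chs <- which(montage$roi == b$roi)
      if (!length(chs)) {
        warning("burst ROI absent from montage: ", b$roi)
        next
      }
      onsets <- events$onset[events$role == b$role]
      if (!length(onsets)) stop("burst role absent from schedule: ", b$role)
      bp <- designBandpass(c(b$f_lo, b$f_hi), fs)
      sigmaEnv <- b$duration / 2
      wfac <- envelopeWindowFactor(sigmaEnv)
      ratio <- 10^(b$amplitude * sigmaDb / 10) - 1
      for (ch in chs) {
        bg <- zeroPhase(bp, sig[, ch])
        p0 <- mean(bg^2)
        amp <- sqrt(ratio * p0 / wfac)
        carrier <- zeroPhase(bp, rnorm(n))
        carrier <- carrier / sqrt(mean(carrier^2))
        env <- numeric(n)
        half <- ceiling(3.5 * sigmaEnv * fs)
        for (on in onsets) {
          c0 <- round((on + b$latency) * fs) + 1L
          idx <- max(1L, c0 - half):min(n, c0 + half)
          env[idx] <- pmax(env[idx],
                           exp(-((idx - c0) / fs)^2 / (2 * sigmaEnv^2)))
        }
        sig[, ch] <- sig[, ch] + amp * env * carrier
      }
    }
  }

  # narrowband phase couplings between ROI pairs
  if (nrow(truth@couplings)) {
    for (r in seq_len(nrow(truth@couplings))) {
      cp <- truth@couplings[r, ]
      onsets <- events$onset[events$role == cp$role]
      win <- cbind(onsets + cp$w_start, onsets + cp$w_end)
      chA <- which(montage$roi == cp$roi_a)
      chB <- which(montage$roi == cp$roi_b)
      zeroA <- numeric(n)
      zeroB <- numeric(n)
      inj <- injectPhaseCoupling(zeroA, zeroB, fs, c(cp$f_lo, cp$f_hi),
                                 cp$plv, cp$lag, win, cp$amplitude)
      sig[, chA] <- sig[, chA] + inj$a
      sig[, chB] <- sig[, chB] + inj$b
    }
  }

  # epileptiform spikes: 70 ms biphasic transients at Poisson times
  spikes <- data.frame(channel = character(), time = numeric())
  if (truth@spikeRate > 0) {
    nw <- round(0.07 * fs)
    wshape <- 300 * sin(2 * pi * seq(0, 1, length.out = nw)) *
      0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = nw)))
    for (j in seq_len(nCh)) {
      k <- rpois(1, truth@spikeRate * dur / 60)
      if (!k) next
      st <- sort(runif(k, 0.1, dur - 0.2))
      for (s0 in st) {
        i1 <- round(s0 * fs) + 1L
        idx <- i1:(i1 + nw - 1L)
        keep <- idx <= n
        sig[idx[keep], j] <- sig[idx[keep], j] + wshape[keep]
      }
      spikes <- rbind(spikes,
                      data.frame(channel = montage$channel[j], time = st))
    }
  }

  chans <- data.frame(name = montage$channel, subject = montage$subject,
                      shank = NA_character_, contact = NA_integer_,
                      roi = montage$roi, flags = NA_character_)
  rec <- Recording(sig, fs, chans)
  new("SimulatedDataset", recording = rec, events = events,
      montage = montage, truth = truth, spikes = spikes,
      seed = as.integer(seed))
}
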