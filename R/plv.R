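# Time-resolved phase-locking-value (PLV) connectivity: filter-Hilbert
# narrowband phases, across-trial PLV per within-subject channel pair,
# baseline normalization, band averaging, ROI-pair pooling, global PLV,
# onset/peak/offset detection and top-pair ordering.

#' Narrow frequency bands for the filter-Hilbert decomposition
#'
#' The canonical band edges: delta 0.1-3 Hz, theta 3-7 Hz, alpha 7-12 Hz,
#' then 4-Hz-wide bands up to `fmax`.
#'
#' @param fmax top band edge (Hz), default 120.
#' @return data.frame (name, f_lo, f_hi).
#' @export
bandSpec <- function(fmax = 120) {
  lo <- c(0.1, 3, 7, seq(12, fmax - 4, by = 4))
  hi <- c(3, 7, 12, seq(16, fmax, by = 4))
  name <- c("delta", "theta", "alpha", paste0("b", lo[-(1:3)], "_", hi[-(1:3)]))
  data.frame(name = name, f_lo = lo, f_hi = hi)
}

namedBandRange <- function(band) {
  switch(band,
         delta = c(0.1, 3), theta = c(3, 7), alpha = c(7, 12),
         stop("unknown band label: ", band))
}

#' Narrowband instantaneous phases (filter-Hilbert)
#'
#' Per band, zero-phase band-pass filtering (Butterworth, 6th order) of each
#' channel and trial on the full (uncropped) extraction window to protect
#' the edges, then the instantaneous phase of the analytic signal (Hilbert
#' transform). Phases are returned at the requested output times only
#' (by default the spectrogram hop grid restricted to `cropWindow`).
#'
#' @param trials a [TrialTensor-class] on the wide extraction window.
#' @param bands data.frame (name, f_lo, f_hi); see [bandSpec()].
#' @param outTimes output time stamps (s); default: 31.25 ms hop grid.
#' @param cropWindow window (s) the output grid is restricted to.
#' @param hopSamples,winS hop and window used to build the default grid
#'   (matching [multitaperSpectrogram()]).
#' @return list with elements phases (array time x band x channel x trial),
#'   times, bands.
#' @export
narrowbandPhases <- function(trials, bands = bandSpec(120)[1:2, ],
                             outTimes = NULL, cropWindow = c(-1, 6),
                             hopSamples = 16L, winS = 0.5) {
  stopifnot(is(trials, "TrialTensor"))
  fs <- trials@fs
  if (any(bands$f_hi >= fs / 2)) stop("band above the Nyquist frequency")
  if (is.null(outTimes)) {
    grid <- windowCenters(trials@time, round(winS * fs), hopSamples)
    outTimes <- grid[grid >= cropWindow[1] - 1e-9 & grid <= cropWindow[2] + 1e-9]
  }
  tol <- 0.5 / fs
  outIdx <- vapply(outTimes, function(t0) which.min(abs(trials@time - t0)), 0L)
  if (max(abs(trials@time[outIdx] - outTimes)) > 1 / fs)
    stop("output times not covered by the trial window")
  d <- dim(trials@data)
  nB <- nrow(bands)
  ph <- array(NA_real_, c(length(outIdx), nB, d[2], d[3]))
  flat <- matrix(trials@data, d[1], d[2] * d[3])
  for (b in seq_len(nB)) {
    filt <- designBandpass(c(bands$f_lo[b], bands$f_hi[b]), fs)
    xf <- zeroPhase(filt, flat)
    phase <- Arg(analyticSignal(xf))
    ph[, b, , ] <- array(phase[outIdx, ], c(length(outIdx), d[2], d[3]))
  }
  list(phases = ph, times = trials@time[outIdx], bands = bands)
}

#' Phase-locking value between two channels
#'
#' PLV(t) = |(1/N) sum over trials of exp(i * (phiM - phiN))|, in [0, 1].
#'
#' @param phiM,phiN phase matrices (time x trial), radians.
#' @return numeric vector of PLV values per time point.
#' @export
plvPair <- function(phiM, phiN) {
  phiM <- as.matrix(phiM); phiN <- as.matrix(phiN)
  if (!all(dim(phiM) == dim(phiN)))
    stop("both channels must carry the same trial count")
  if (ncol(phiM) < 20)
    warning("fewer than 20 trials: the PLV estimator is noisy")
  Mod(rowMeans(exp(1i * (phiM - phiN))))
}

#' Across-trial PLV for all within-subject channel pairs
#'
#' Enumerates channel pairs within each subject whose two channels lie in
#' different ROIs, and computes the raw PLV time course per pair and band on
#' the spectrogram hop grid. Pairs never mix subjects (enumeration is per
#' subject by construction).
#'
#' @param trials a [TrialTensor-class] on the wide extraction window.
#' @param map optional channel map (subject, channel, roi).
#' @param bands band table (default delta and theta).
#' @param cropWindow output window (s).
#' @param hopSamples,winS output-grid parameters.
#' @return a raw [PLVSet-class].
#' @export
plvConnectivity <- function(trials, map = NULL, bands = bandSpec(120)[1:2, ],
                            cropWindow = c(-1, 6), hopSamples = 16L,
                            winS = 0.5) {
  stopifnot(is(trials, "TrialTensor"))
  ch <- trials@channels
  roi <- ch$roi
  if (!is.null(map)) {
    map <- as.data.frame(map)
    key <- paste(ch$subject, ch$name, sep = "\r")
    roi <- map$roi[match(key, paste(map$subject, map$channel, sep = "\r"))]
  }
  np <- narrowbandPhases(trials, bands, cropWindow = cropWindow,
                         hopSamples = hopSamples, winS = winS)
  pairs <- list()
  for (s in unique(ch$subject)) {
    idx <- which(ch$subject == s & !is.na(roi))
    if (length(idx) < 2) next
    cmb <- utils::combn(idx, 2)
    keep <- roi[cmb[1, ]] != roi[cmb[2, ]]
    cmb <- cmb[, keep, drop = FALSE]
    if (ncol(cmb))
      pairs[[length(pairs) + 1L]] <- data.frame(
        subject = s, iA = cmb[1, ], iB = cmb[2, ],
        chA = ch$name[cmb[1, ]], chB = ch$name[cmb[2, ]],
        roiA = roi[cmb[1, ]], roiB = roi[cmb[2, ]])
  }
  if (!length(pairs)) stop("no within-subject channel pair spans two ROIs")
  pairs <- do.call(rbind, pairs)
  nB <- nrow(bands)
  plv <- array(NA_real_, c(length(np$times), nB, nrow(pairs)))
  for (p in seq_len(nrow(pairs))) {
    for (b in seq_len(nB)) {
      plv[, b, p] <- suppressWarnings(
        plvPair(np$phases[, b, pairs$iA[p], ], np$phases[, b, pairs$iB[p], ]))
    }
  }
  pairs$iA <- NULL; pairs$iB <- NULL
  rownames(pairs) <- NULL
  new("PLVSet", plv = plv, times = np$times, bands = bands, pairs = pairs,
      normalized = FALSE, nTrials = dim(trials@data)[3],
      baselineWindow = numeric(0))
}

#' Baseline-normalize a PLV set
#'
#' Per channel pair and narrow band, z-scores the PLV time course against
#' its own baseline-interval distribution and scales by 100 (baseline mean
#' 0%, SD 100%), mirroring the spectral normalization.
#'
#' @param p a raw [PLVSet-class].
#' @param baseline c(start, end) s, default [-1, -0.25].
#' @return the normalized [PLVSet-class].
#' @export
normalizePlv <- function(p, baseline = c(-1, -0.25)) {
  stopifnot(is(p, "PLVSet"))
  if (p@normalized) stop("PLV set is already normalized")
  bIdx <- which(p@times >= baseline[1] - 1e-9 & p@times <= baseline[2] + 1e-9)
  if (length(bIdx) < 2) stop("baseline interval holds fewer than 2 time points")
  out <- p@plv
  for (j in seq_len(dim(out)[3])) {
    for (b in seq_len(dim(out)[2])) {
      base <- p@plv[bIdx, b, j]
      mu <- mean(base, na.rm = TRUE)
      sg <- sd(base, na.rm = TRUE)
      if (!is.finite(sg) || sg <= 1e-12)
        stop("zero baseline variance for pair ", p@pairs$chA[j], "-",
             p@pairs$chB[j], ", band ", p@bands$name[b])
      out[, b, j] <- 100 * (p@plv[, b, j] - mu) / sg
    }
  }
  new("PLVSet", plv = out, times = p@times, bands = p@bands, pairs = p@pairs,
      normalized = TRUE, nTrials = p@nTrials, baselineWindow = baseline)
}

#' Average a PLV set over a named frequency range
#'
#' Means the (normalized) PLV over all narrow bands contained in the named
#' range (delta 0.1-3, theta 3-7, alpha 7-12 Hz) or an explicit c(lo, hi).
#'
#' @param p a [PLVSet-class].
#' @param band band label or c(lo, hi) Hz.
#' @return a [PLVSet-class] with a single band.
#' @export
bandAverage <- function(p, band = "delta") {
  stopifnot(is(p, "PLVSet"))
  rng <- if (is.character(band)) namedBandRange(band) else band
  sel <- which(p@bands$f_lo >= rng[1] - 1e-9 & p@bands$f_hi <= rng[2] + 1e-9)
  if (!length(sel)) stop("no narrow band inside the requested range")
  avg <- apply(p@plv[, sel, , drop = FALSE], c(1, 3), mean, na.rm = TRUE)
  newBands <- data.frame(name = if (is.character(band)) band else
                           paste0(rng[1], "-", rng[2]),
                         f_lo = rng[1], f_hi = rng[2])
  arr <- array(avg, c(dim(avg)[1], 1L, dim(avg)[2]))
  new("PLVSet", plv = arr, times = p@times, bands = newBands,
      pairs = p@pairs, normalized = p@normalized, nTrials = p@nTrials,
      baselineWindow = p@baselineWindow)
}

#' ROI-pair PLV time course
#'
#' Mean over all within-subject channel pairs connecting the two ROIs.
#' Connections contributed by fewer than two subjects are reported as
#' absent.
#'
#' @param p a single-band [PLVSet-class] (see [bandAverage()]).
#' @param roiA,roiB the two (distinct) ROI labels.
#' @return list(series, nPairs, nSubjects); series is NULL when fewer than
#'   two subjects contribute (absent connection).
#' @export
roiPairPlv <- function(p, roiA, roiB) {
  stopifnot(is(p, "PLVSet"))
  if (identical(roiA, roiB)) stop("ROI pair must be two distinct ROIs")
  sel <- which((p@pairs$roiA == roiA & p@pairs$roiB == roiB) |
                 (p@pairs$roiA == roiB & p@pairs$roiB == roiA))
  subj <- unique(p@pairs$subject[sel])
  if (length(subj) < 2)
    return(list(series = NULL, nPairs = length(sel),
                nSubjects = length(subj)))
  series <- apply(p@plv[, , sel, drop = FALSE], 1, mean, na.rm = TRUE)
  list(series = series, nPairs = length(sel), nSubjects = length(subj))
}

#' Global network PLV with significance
#'
#' Mean and SEM across all channel pairs, with a per-time-point two-sided
#' Wilcoxon rank-sum test of the pair values against the pooled baseline
#' values, FDR-corrected over time points.
#'
#' @param p a single-band [PLVSet-class].
#' @param baseline baseline interval (s); defaults to the normalization
#'   window.
#' @param alpha level on the FDR-adjusted p-values (default 0.05).
#' @param fdrMethod "bh" or "by".
#' @return data.frame (time, plv, sem, p, pAdj, sig).
#' @export
globalPlv <- function(p, baseline = NULL, alpha = 0.05, fdrMethod = "bh") {
  stopifnot(is(p, "PLVSet"))
  if (dim(p@plv)[3] < 2) stop("at least 2 channel pairs required")
  if (dim(p@plv)[2] != 1) stop("band-average the PLV set first")
  if (is.null(baseline))
    baseline <- if (length(p@baselineWindow)) p@baselineWindow else c(-1, -0.25)
  X <- p@plv[, 1, ]                      # time x pair
  m <- rowMeans(X, na.rm = TRUE)
  sem <- apply(X, 1, function(v) {
    v <- v[!is.na(v)]
    if (length(v) > 1) sd(v) / sqrt(length(v)) else 0
  })
  bIdx <- which(p@times >= baseline[1] - 1e-9 & p@times <= baseline[2] + 1e-9)
  basePool <- as.vector(X[bIdx, ])
  basePool <- basePool[!is.na(basePool)]
  pv <- ranksumVec(X, basePool)
  fc <- fdrCorrect(pv, q = alpha, method = fdrMethod)
  data.frame(time = p@times, plv = m, sem = sem, p = pv, pAdj = fc$pAdj,
             sig = fc$mask)
}

#' Onset, peak and offset of a connectivity time course
#'
#' Per stimulus period: the peak is the maximum of the series within the
#' period (ties to the earliest point); the onset is the maximum and the
#' offset the minimum of the first derivative, estimated by three-point
#' stencils and smoothed with a zero-phase 5 Hz low-pass (Butterworth,
#' 6th order) in the hop-grid sampling rate. Onset and offset must be
#' interior local extrema of the smoothed derivative; on a monotone series
#' they are reported absent (NA).
#'
#' @param series numeric time course on the hop grid.
#' @param times time stamps (s) of the series.
#' @param periods data.frame (name, start, end) of the search windows, e.g.
#'   operand periods [onset, onset + 1.05] s.
#' @return data.frame (period, onset, peak, offset) in seconds.
#' @export
detectTimepoints <- function(series, times, periods) {
  stopifnot(length(series) == length(times))
  dt <- median(diff(times))
  fsHop <- 1 / dt
  n <- length(series)
  der <- rep(NA_real_, n)
  der[2:(n - 1)] <- (series[3:n] - series[1:(n - 2)]) / (2 * dt)
  der[1] <- der[2]; der[n] <- der[n - 1]
  if (5 < fsHop / 2) {
    lp <- designLowpass(5, fsHop, order = 6L)
    der <- zeroPhase(lp, der)
  }
  tolD <- 1e-6 * max(abs(der), na.rm = TRUE)
  isLocalMax <- function(v, i) i > 1 && i < length(v) &&
    v[i] >= v[i - 1] && v[i] >= v[i + 1] &&
    (v[i] > v[i - 1] + tolD || v[i] > v[i + 1] + tolD)
  out <- list()
  for (r in seq_len(nrow(periods))) {
    idx <- which(times >= periods$start[r] - 1e-9 &
                   times <= periods$end[r] + 1e-9)
    if (length(idx) < 3 || all(!is.finite(series[idx]))) {
      out[[r]] <- data.frame(period = periods$name[r], onset = NA_real_,
                             peak = NA_real_, offset = NA_real_)
      next
    }
    pk <- idx[which.max(series[idx])]
    peakT <- if (diff(range(series[idx], na.rm = TRUE)) < 1e-12)
      NA_real_ else times[pk]
    dIdx <- idx
    iOn <- dIdx[which.max(der[dIdx])]
    iOff <- dIdx[which.min(der[dIdx])]
    # onset needs a rising (positive) derivative maximum, offset a falling
    # (negative) derivative minimum; both must be interior local extrema
    onT <- if (der[iOn] > 0 && isLocalMax(der, iOn)) times[iOn] else NA_real_
    offT <- if (der[iOff] < 0 && isLocalMax(-der, iOff)) times[iOff]
            else NA_real_
    out[[r]] <- data.frame(period = periods$name[r], onset = onT,
                           peak = peakT, offset = offT)
  }
  do.call(rbind, out)
}

#' Strongest ROI-pair connections, ordered by peak latency
#'
#' Ranks ROI pairs by their maximum normalized PLV within a period, keeps
#' those exceeding the threshold (default 3 baseline SDs = 300%), takes the
#' top n by maximum value and orders them by the latency of the maximum.
#' Pairs contributed by fewer than two subjects are excluded.
#'
#' @param p a normalized, single-band [PLVSet-class].
#' @param period c(start, end) s.
#' @param n number of pairs to keep (default 15).
#' @param threshold threshold in percent (default 300).
#' @return data.frame (roiA, roiB, maxPlv, latency), ordered by latency;
#'   may hold fewer than n rows.
#' @export
topPairs <- function(p, period, n = 15L, threshold = 300) {
  stopifnot(is(p, "PLVSet"))
  if (dim(p@plv)[2] != 1) stop("band-average the PLV set first")
  combos <- unique(data.frame(
    roiA = pmin(p@pairs$roiA, p@pairs$roiB),
    roiB = pmax(p@pairs$roiA, p@pairs$roiB)))
  tIdx <- which(p@times >= period[1] - 1e-9 & p@times <= period[2] + 1e-9)
  rows <- list()
  for (r in seq_len(nrow(combos))) {
    rp <- roiPairPlv(p, combos$roiA[r], combos$roiB[r])
    if (is.null(rp$series)) next
    s <- rp$series[tIdx]
    pk <- which.max(s)
    if (s[pk] < threshold) next
    rows[[length(rows) + 1L]] <- data.frame(
      roiA = combos$roiA[r], roiB = combos$roiB[r],
      maxPlv = s[pk], latency = p@times[tIdx][pk] - period[1])
  }
  if (!length(rows))
    return(data.frame(roiA = character(), roiB = character(),
                      maxPlv = numeric(), latency = numeric()))
  out <- do.call(rbind, rows)
  out <- out[order(-out$maxPlv), , drop = FALSE]
  out <- head(out, n)
  out <- out[order(out$latency), , drop = FALSE]
  rownames(out) <- NULL
  out
}
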