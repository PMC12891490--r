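# High-gamma band (52-120 Hz) activity: extraction from the normalized
# spectrogram, ROI profiles with significance masks, per-channel indicators
# (M, T, b), stimulus-period contrasts and the peak-latency ordering of the
# activation cascade.

# Frequency bins entering the high-gamma average: bins inside [lo, hi]
# whose +-1 Hz extent does not intersect the notched 100 Hz harmonic band
# [98, 102]. The 50 Hz harmonic lies below the 52 Hz band edge.
hgbBins <- function(freqs, band = c(52, 120), harmonic = c(98, 102)) {
  inBand <- freqs >= band[1] - 1e-9 & freqs <= band[2] + 1e-9
  nearHarm <- (freqs + 1) >= harmonic[1] - 1e-9 & (freqs - 1) <= harmonic[2] + 1e-9
  which(inBand & !nearHarm)
}

#' Extract the high-gamma-band activity
#'
#' Mean of the normalized spectrogram across the 52-120 Hz bins, excluding
#' the notched-out 100 Hz harmonic bins. Missing (masked) windows propagate.
#' Also stores the single-channel, trial-averaged series.
#'
#' @param spec a normalized [Spectrogram-class].
#' @param band c(lo, hi) Hz (default c(52, 120)).
#' @return an [HGBSeries-class] in percent-of-baseline units.
#' @export
extractHgb <- function(spec, band = c(52, 120)) {
  stopifnot(is(spec, "Spectrogram"))
  if (!spec@normalized) stop("spectrogram must be baseline-normalized first")
  bins <- hgbBins(spec@freqs, band)
  if (!length(bins)) stop("no qualifying frequency bins in ", band[1], "-",
                          band[2], " Hz")
  d <- dim(spec@values)
  sub <- spec@values[, bins, , , drop = FALSE]
  perTrial <- apply(sub, c(1, 3, 4), function(v)
    if (all(is.na(v))) NA_real_ else mean(v))
  trialAvg <- apply(perTrial, c(1, 2), mean, na.rm = TRUE)
  new("HGBSeries", perTrial = perTrial, trialAvg = trialAvg,
      times = spec@times, channels = spec@channels, trials = spec@trials,
      hop = spec@hop, fs = spec@fs, band = band)
}

#' Pool high-gamma series across subjects
#'
#' Concatenates the channel dimension of per-subject [HGBSeries-class]
#' objects sharing a time axis, so that ROI grand averages run across all
#' channels of all subjects.
#'
#' @param hList list of [HGBSeries-class] objects.
#' @return a pooled [HGBSeries-class] (per-trial data are dropped; the
#'   pooled object carries the trial-averaged series only).
#' @export
combineHgb <- function(hList) {
  stopifnot(length(hList) >= 1L)
  t0 <- hList[[1]]@times
  for (h in hList)
    if (length(h@times) != length(t0) || max(abs(h@times - t0)) > 1e-9)
      stop("HGB series must share one time axis")
  trialAvg <- do.call(cbind, lapply(hList, function(h) h@trialAvg))
  channels <- do.call(rbind, lapply(hList, function(h) h@channels))
  rownames(channels) <- NULL
  trials <- data.frame()
  attr(trials, "roleOnsets") <- attr(hList[[1]]@trials, "roleOnsets")
  new("HGBSeries", perTrial = array(NA_real_, c(length(t0), 0, 0)),
      trialAvg = trialAvg, times = t0, channels = channels,
      trials = trials, hop = hList[[1]]@hop, fs = hList[[1]]@fs,
      band = hList[[1]]@band)
}

#' ROI-level high-gamma profile with significance mask
#'
#' Grand average of the single-channel, trial-averaged high-gamma series
#' across all channels of all subjects in the ROI, with the SEM across
#' channels and a per-time-point significance mask: at each time point the
#' distribution of channel values is tested against the pooled baseline
#' values of the same channels (two-sided Wilcoxon rank-sum), FDR-corrected
#' across time points.
#'
#' @param h an [HGBSeries-class] (single subject or pooled).
#' @param map optional channel map (subject, channel, roi).
#' @param roi the ROI label.
#' @param baseline baseline interval (s).
#' @param alpha significance level applied to the FDR-adjusted p-values
#'   (default 0.001, the activation-mask convention).
#' @param fdrMethod "bh" or "by".
#' @return data.frame (time, hgb, sem, p, pAdj, sig) with attributes
#'   nChannels and nSubjects.
#' @export
roiHgb <- function(h, map = NULL, roi, baseline = c(-1, -0.25),
                   alpha = 0.001, fdrMethod = "bh") {
  stopifnot(is(h, "HGBSeries"))
  chIdx <- roiChannelIndices(h@channels, map, roi)
  X <- h@trialAvg[, chIdx, drop = FALSE]       # time x channels
  m <- rowMeans(X, na.rm = TRUE)
  sem <- apply(X, 1, function(v) {
    v <- v[!is.na(v)]
    if (length(v) > 1) sd(v) / sqrt(length(v)) else 0
  })
  bIdx <- which(h@times >= baseline[1] - 1e-9 & h@times <= baseline[2] + 1e-9)
  basePool <- as.vector(X[bIdx, , drop = FALSE])
  basePool <- basePool[!is.na(basePool)]
  p <- ranksumVec(X, basePool)
  pAdj <- fdrCorrect(p, q = alpha, method = fdrMethod)$pAdj
  out <- data.frame(time = h@times, hgb = m, sem = sem, p = p, pAdj = pAdj,
                    sig = !is.na(pAdj) & pAdj <= alpha)
  subj <- h@channels$subject[chIdx]
  attr(out, "nChannels") <- length(chIdx)
  attr(out, "nSubjects") <- length(unique(subj[!is.na(subj)]))
  out
}

#' Per-channel indicators of high-gamma activity
#'
#' Three indicators over the analysis interval (default [0, 5] s after the
#' first operand): M, the time-mean of the absolute trial-averaged series;
#' T, the summed duration of time points whose across-trial distribution
#' differs from the channel's pooled baseline single-trial values
#' (two-sided Wilcoxon rank-sum, FDR-corrected across all time points and
#' channels, default alpha 0.05); and b, the ordinary least-squares slope
#' of the trial-averaged series on time.
#'
#' @param h an [HGBSeries-class] with per-trial data.
#' @param interval c(start, end) s.
#' @param baseline baseline interval (s).
#' @param alpha level on the FDR-adjusted p-values for T.
#' @param fdrMethod "bh" or "by".
#' @return data.frame (channel, M, T, b).
#' @export
hgbIndicators <- function(h, interval = c(0, 5), baseline = c(-1, -0.25),
                          alpha = 0.05, fdrMethod = "bh") {
  stopifnot(is(h, "HGBSeries"))
  if (!dim(h@perTrial)[3])
    stop("per-trial data required (pooled series carry trial averages only)")
  tIdx <- which(h@times >= interval[1] - 1e-9 & h@times <= interval[2] + 1e-9)
  if (!length(tIdx)) stop("indicator interval outside the time axis")
  bIdx <- which(h@times >= baseline[1] - 1e-9 & h@times <= baseline[2] + 1e-9)
  nCh <- dim(h@perTrial)[2]
  M <- numeric(nCh); b <- numeric(nCh)
  pmat <- matrix(NA_real_, length(tIdx), nCh)
  for (ch in seq_len(nCh)) {
    avg <- h@trialAvg[tIdx, ch]
    M[ch] <- mean(abs(avg), na.rm = TRUE)
    tt <- h@times[tIdx]
    ok <- !is.na(avg)
    b[ch] <- if (sum(ok) > 1)
      sum((tt[ok] - mean(tt[ok])) * (avg[ok] - mean(avg[ok]))) /
        sum((tt[ok] - mean(tt[ok]))^2) else NA_real_
    basePool <- as.vector(h@perTrial[bIdx, ch, ])
    basePool <- basePool[!is.na(basePool)]
    pmat[, ch] <- ranksumVec(h@perTrial[tIdx, ch, , drop = TRUE], basePool)
  }
  adj <- fdrCorrect(as.vector(pmat), q = alpha, method = fdrMethod)$pAdj
  sig <- matrix(!is.na(adj) & adj <= alpha, length(tIdx), nCh)
  Tdur <- colSums(sig) * h@hop / h@fs
  data.frame(channel = h@channels$name, M = M, T = Tdur, b = b)
}

# Stimulus-period windows [onset, onset + duration) relative to the anchor,
# from the role onsets stored at extraction time.
rolePeriodWindows <- function(trialsMeta, roles, duration = 1.05) {
  rel <- attr(trialsMeta, "roleOnsets")
  if (is.null(rel)) stop("trial metadata carry no role-onset information")
  missing <- setdiff(roles, names(rel))
  if (length(missing)) stop("role(s) absent: ", paste(missing, collapse = ", "))
  data.frame(role = roles, start = as.numeric(rel[roles]),
             end = as.numeric(rel[roles]) + duration)
}

#' Mean high-gamma activity per stimulus period
#'
#' Per channel, the time-mean of the trial-averaged series over each role's
#' presentation period [onset, onset + 1.05) s.
#'
#' @param h an [HGBSeries-class].
#' @param roles stimulus roles (default operands and operators).
#' @param duration period length (s); the stimulus duration.
#' @return matrix channels x roles (%).
#' @export
periodMeans <- function(h, roles = c("N1", "O1", "N2", "O2", "N3"),
                        duration = 1.05) {
  stopifnot(is(h, "HGBSeries"))
  wins <- rolePeriodWindows(h@trials, roles, duration)
  out <- matrix(NA_real_, ncol(h@trialAvg), length(roles),
                dimnames = list(h@channels$name, roles))
  for (r in seq_len(nrow(wins))) {
    tIdx <- which(h@times >= wins$start[r] - 1e-9 & h@times < wins$end[r] - 1e-9)
    out[, r] <- colMeans(h@trialAvg[tIdx, , drop = FALSE], na.rm = TRUE)
  }
  out
}

#' Compare mean high-gamma activity between stimulus periods
#'
#' Per ROI and period pair, a paired two-tailed sign test on the channels'
#' mean activities, FDR-corrected across all ROI x pair tests.
#'
#' @param means channels x roles matrix from [periodMeans()].
#' @param channels channel table aligned with the rows of `means`.
#' @param map optional channel map (subject, channel, roi).
#' @param pairs list of role pairs to test.
#' @param q FDR level.
#' @param fdrMethod "bh" or "by".
#' @return data.frame (roi, pair, nChannels, direction, p, pAdj, sig).
#' @export
comparePeriods <- function(means, channels, map = NULL,
                           pairs = list(c("N1", "N2"), c("N1", "N3"),
                                        c("N2", "N3"), c("O1", "O2")),
                           q = 0.05, fdrMethod = "bh") {
  if (nrow(means) < 2) stop("at least 2 channels required")
  if (nrow(means) < 6)
    message("fewer than 6 channels: the sign test has little power")
  rois <- if (is.null(map)) unique(channels$roi[!is.na(channels$roi)])
          else unique(as.data.frame(map)$roi)
  rows <- list()
  for (roi in rois) {
    chIdx <- tryCatch(roiChannelIndices(channels, map, roi),
                      error = function(e) integer())
    if (length(chIdx) < 2) next
    for (pr in pairs) {
      d <- means[chIdx, pr[2]] - means[chIdx, pr[1]]
      d <- d[!is.na(d)]
      st <- signTest(d)
      rows[[length(rows) + 1L]] <- data.frame(
        roi = roi, pair = paste(pr[1], "vs", pr[2]),
        nChannels = length(d),
        direction = if (is.na(st$p)) NA_character_
                    else if (median(d) > 0) "increase"
                    else if (median(d) < 0) "decrease" else "none",
        p = st$p)
    }
  }
  out <- do.call(rbind, rows)
  fc <- fdrCorrect(out$p, q = q, method = fdrMethod)
  out$pAdj <- fc$pAdj
  out$sig <- fc$mask
  out
}

#' Peak-latency ordering of the activation cascade
#'
#' Per operand period, selects the ROIs whose ROI-level high-gamma peak
#' exceeds the activation threshold (default 2 baseline SDs = 200%) and
#' orders them by the latency of the maximum (ties broken to the earliest
#' time point). Pairwise differences between ROIs are tested on the
#' distributions of single-channel, trial-averaged peak latencies
#' (two-sided Wilcoxon rank-sum, FDR-corrected).
#'
#' @param h an [HGBSeries-class] (single subject or pooled).
#' @param map optional channel map.
#' @param rois ROIs to consider; defaults to all mapped ROIs.
#' @param periods operand roles (default N1, N2, N3).
#' @param threshold activation threshold in percent (default 200).
#' @param duration period length (s).
#' @param alpha level on the FDR-adjusted pairwise p-values (default 0.05).
#' @param fdrMethod "bh" or "by".
#' @return named list per period: list(ordering = data.frame(roi, latency,
#'   peak), pairwise = data.frame(roiA, roiB, p, pAdj, sig)).
#' @export
latencyOrdering <- function(h, map = NULL, rois = NULL,
                            periods = c("N1", "N2", "N3"), threshold = 200,
                            duration = 1.05, alpha = 0.05, fdrMethod = "bh") {
  stopifnot(is(h, "HGBSeries"))
  if (is.null(rois))
    rois <- if (is.null(map)) unique(h@channels$roi[!is.na(h@channels$roi)])
            else unique(as.data.frame(map)$roi)
  wins <- rolePeriodWindows(h@trials, periods, duration)
  out <- list()
  for (r in seq_len(nrow(wins))) {
    tIdx <- which(h@times >= wins$start[r] - 1e-9 & h@times <= wins$end[r] + 1e-9)
    tt <- h@times[tIdx]
    peakRows <- list(); latDist <- list()
    for (roi in rois) {
      chIdx <- tryCatch(roiChannelIndices(h@channels, map, roi),
                        error = function(e) integer())
      if (!length(chIdx)) next
      series <- rowMeans(h@trialAvg[tIdx, chIdx, drop = FALSE], na.rm = TRUE)
      pk <- which.max(series)   # ties -> earliest
      peakRows[[roi]] <- data.frame(roi = roi, latency = tt[pk] - wins$start[r],
                                    peak = series[pk])
      latDist[[roi]] <- apply(h@trialAvg[tIdx, chIdx, drop = FALSE], 2,
                              function(v) tt[which.max(v)] - wins$start[r])
    }
    ord <- do.call(rbind, peakRows)
    keep <- ord$peak >= threshold
    if (!any(keep)) {
      warning("no ROI crosses the ", threshold, "% threshold in period ",
              wins$role[r])
      ord <- ord[0, ]
    } else ord <- ord[keep, , drop = FALSE]
    ord <- ord[order(ord$latency), , drop = FALSE]
    rownames(ord) <- NULL
    pw <- NULL
    kept <- ord$roi
    if (length(kept) >= 2) {
      cmb <- utils::combn(kept, 2)
      pw <- data.frame(roiA = cmb[1, ], roiB = cmb[2, ],
                       p = apply(cmb, 2, function(pair)
                         rankSumTest(latDist[[pair[1]]],
                                     latDist[[pair[2]]])$p))
      fc <- fdrCorrect(pw$p, q = alpha, method = fdrMethod)
      pw$pAdj <- fc$pAdj
      pw$sig <- fc$mask
    }
    out[[wins$role[r]]] <- list(ordering = ord, pairwise = pw)
  }
  out
}

#' Condition contrasts of high-gamma activity
#'
#' Tests whether period-mean high-gamma activity differs between condition
#' levels, per ROI, with a paired two-tailed sign test across channels and
#' FDR correction across ROIs. For `contrast = "format"` the function also
#' returns, per ROI, the matrix of Pearson correlation coefficients between
#' the format-specific trial-averaged time courses and its mean (the
#' format-similarity index). For `contrast = "decade_crossing"` the paired
#' difference per channel is the mean activity in the crossing operand's
#' period minus the non-crossing operand's period, within "difficult"
#' trials. For `contrast = "operator_sign"` trials are split by the first
#' operator's sign over the O1 period.
#'
#' @param h an [HGBSeries-class] with per-trial data.
#' @param contrast one of "format", "operator_sign", "decade_crossing".
#' @param map optional channel map.
#' @param q FDR level (default 0.05).
#' @param window analysis window (s) for format correlations (default
#'   c(0, 6)).
#' @param fdrMethod "bh" or "by".
#' @return list(tests = data.frame(roi, p, pAdj, sig, direction),
#'   cc = for "format", data.frame(roi, meanCC)).
#' @export
conditionContrasts <- function(h, contrast = c("format", "operator_sign",
                                               "decade_crossing"),
                               map = NULL, q = 0.05, window = c(0, 6),
                               fdrMethod = "bh") {
  stopifnot(is(h, "HGBSeries"))
  contrast <- match.arg(contrast)
  if (!dim(h@perTrial)[3]) stop("per-trial data required")
  meta <- h@trials
  rois <- if (is.null(map)) unique(h@channels$roi[!is.na(h@channels$roi)])
          else unique(as.data.frame(map)$roi)
  condMean <- function(chIdx, trIdx, win) {
    tIdx <- which(h@times >= win[1] - 1e-9 & h@times < win[2] - 1e-9)
    vapply(chIdx, function(ch)
      mean(h@perTrial[tIdx, ch, trIdx], na.rm = TRUE), 0)
  }
  rows <- list(); ccRows <- list()
  for (roi in rois) {
    chIdx <- tryCatch(roiChannelIndices(h@channels, map, roi),
                      error = function(e) integer())
    if (length(chIdx) < 2) next
    if (contrast == "format") {
      levs <- sort(unique(meta$format))
      if (any(vapply(levs, function(l) sum(meta$format == l), 0L) == 0))
        stop("a format level has zero trials")
      tIdx <- which(h@times >= window[1] - 1e-9 & h@times <= window[2] + 1e-9)
      curves <- vapply(levs, function(l) {
        trIdx <- which(meta$format == l)
        rowMeans(apply(h@perTrial[tIdx, chIdx, trIdx, drop = FALSE],
                       c(1, 2), mean, na.rm = TRUE), na.rm = TRUE)
      }, numeric(length(tIdx)))
      cm <- stats::cor(curves, use = "pairwise.complete.obs")
      ccRows[[roi]] <- data.frame(roi = roi,
                                  meanCC = mean(cm[upper.tri(cm)]))
      # sign test on the two most frequent formats' period means
      top2 <- names(sort(table(meta$format), decreasing = TRUE))[1:2]
      d <- condMean(chIdx, which(meta$format == top2[1]), window) -
        condMean(chIdx, which(meta$format == top2[2]), window)
    } else if (contrast == "operator_sign") {
      wins <- rolePeriodWindows(meta, "O1")
      win <- c(wins$start[1], wins$end[1])
      aIdx <- which(meta$op1 == "+"); bIdx <- which(meta$op1 == "-")
      if (!length(aIdx) || !length(bIdx))
        stop("an operator-sign level has zero trials")
      d <- condMean(chIdx, aIdx, win) - condMean(chIdx, bIdx, win)
    } else {
      diffTr <- which(meta$difficulty == "difficult" & !is.na(meta$decade_role))
      if (!length(diffTr)) stop("no difficult trials with a decade crossing")
      winsN <- rolePeriodWindows(meta, c("N2", "N3"))
      perChan <- matrix(NA_real_, length(chIdx), length(diffTr))
      for (k in seq_along(diffTr)) {
        tr <- diffTr[k]
        cross <- meta$decade_role[tr]
        other <- setdiff(c("N2", "N3"), cross)
        wc <- winsN[winsN$role == cross, ]
        wo <- winsN[winsN$role == other, ]
        tc <- which(h@times >= wc$start - 1e-9 & h@times < wc$end - 1e-9)
        to <- which(h@times >= wo$start - 1e-9 & h@times < wo$end - 1e-9)
        perChan[, k] <- colMeans(h@perTrial[tc, chIdx, tr], na.rm = TRUE) -
          colMeans(h@perTrial[to, chIdx, tr], na.rm = TRUE)
      }
      d <- rowMeans(perChan, na.rm = TRUE)
    }
    d <- d[!is.na(d)]
    st <- signTest(d)
    rows[[length(rows) + 1L]] <- data.frame(
      roi = roi, p = st$p,
      direction = if (is.na(st$p)) NA_character_
                  else if (median(d) > 0) "increase"
                  else if (median(d) < 0) "decrease" else "none")
  }
  tests <- do.call(rbind, rows)
  if (!is.null(tests)) {
    fc <- fdrCorrect(tests$p, q = q, method = fdrMethod)
    tests$pAdj <- fc$pAdj
    tests$sig <- fc$mask
  }
  list(tests = tests,
       cc = if (contrast == "format") do.call(rbind, ccRows) else NULL)
}
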