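# Trigger-based trial extraction, cropping, condition selection and
# behavioural summaries.

#' Extract trials around an anchor stimulus
#'
#' Epochs the continuous recording into D(t, ch, tr). The default window is
#' [-2, 9] s anchored at the N1 onset (t = 0 at the first operand); the
#' window is sample-inclusive at both ends, giving (w2 - w1) * fs + 1
#' samples. Trials whose window overlaps the recording edges are dropped
#' with a warning. The rejection mask is carried through.
#'
#' @param rec a preprocessed [Recording-class].
#' @param events event table (one row per stimulus per trial) with columns
#'   trial, role, onset and per-trial condition columns.
#' @param window c(start, end) in seconds relative to the anchor.
#' @param anchor role whose onset defines t = 0 (default "N1"; use "O1" for
#'   operator-anchored extraction).
#' @return a [TrialTensor-class].
#' @export
extractTrials <- function(rec, events, window = c(-2, 9), anchor = "N1") {
  stopifnot(is(rec, "Recording"))
  events <- as.data.frame(events)
  anch <- events[events$role == anchor, , drop = FALSE]
  if (!nrow(anch)) stop("anchor role ", anchor, " absent from the event table")
  fs <- rec@fs
  nSamp <- round((window[2] - window[1]) * fs) + 1L
  n <- nrow(rec@signal)
  starts <- round(anch$onset * fs) + 1L + round(window[1] * fs)
  ok <- starts >= 1L & (starts + nSamp - 1L) <= n
  if (!any(ok)) stop("zero extractable trials: all windows overlap the edges")
  if (any(!ok))
    warning(sum(!ok), " trial(s) dropped: extraction window overlaps the ",
            "recording edges")
  anch <- anch[ok, , drop = FALSE]
  starts <- starts[ok]
  nCh <- ncol(rec@signal)
  dat <- array(NA_real_, c(nSamp, nCh, nrow(anch)))
  msk <- array(FALSE, c(nSamp, nCh, nrow(anch)))
  for (k in seq_along(starts)) {
    idx <- starts[k]:(starts[k] + nSamp - 1L)
    dat[, , k] <- rec@signal[idx, ]
    msk[, , k] <- rec@mask[idx, ]
  }
  tvec <- window[1] + (seq_len(nSamp) - 1L) / fs
  meta <- anch[, setdiff(names(anch), c("role", "onset")), drop = FALSE]
  rownames(meta) <- NULL
  # keep role onsets relative to the anchor for period definitions
  relOn <- relativeOnsets(events, anchor)
  attr(meta, "roleOnsets") <- relOn
  new("TrialTensor", data = dat, time = tvec, fs = fs,
      channels = rec@channels, trials = meta, mask = msk)
}

# Median onset of each role relative to the anchor role, across trials.
relativeOnsets <- function(events, anchor = "N1") {
  anch <- events[events$role == anchor, c("trial", "onset")]
  names(anch)[2] <- "anchorOnset"
  ev <- merge(events, anch, by = "trial")
  rel <- tapply(ev$onset - ev$anchorOnset, ev$role, median)
  rel <- stats::setNames(as.numeric(rel), names(rel))
  rel[order(rel)]
}

#' Crop a trial tensor to a sub-window
#'
#' Restricts the time axis; metadata are untouched. Cropping to the stored
#' window is the identity, and repeated crops equal a single crop to the
#' intersection.
#'
#' @param trials a [TrialTensor-class].
#' @param window c(start, end) s; must lie within the stored window.
#' @return the cropped [TrialTensor-class].
#' @export
cropTrials <- function(trials, window = c(-1, 6)) {
  stopifnot(is(trials, "TrialTensor"))
  tol <- 0.5 / trials@fs
  if (window[1] < trials@time[1] - tol ||
      window[2] > trials@time[length(trials@time)] + tol)
    stop("crop window [", window[1], ", ", window[2],
         "] lies outside the stored window")
  keep <- which(trials@time >= window[1] - tol & trials@time <= window[2] + tol)
  new("TrialTensor", data = trials@data[keep, , , drop = FALSE],
      time = trials@time[keep], fs = trials@fs, channels = trials@channels,
      trials = trials@trials, mask = trials@mask[keep, , , drop = FALSE])
}

#' Select trials by condition metadata
#'
#' Subsets the trial dimension with a predicate evaluated in the per-trial
#' metadata (e.g. `correct == TRUE`, `format == "dice"`,
#' `op1 == "-" & correct`) or a logical vector.
#'
#' @param trials a [TrialTensor-class].
#' @param predicate an unquoted expression over metadata columns, or a
#'   logical vector of length `nTrials(trials)`.
#' @return the selected [TrialTensor-class].
#' @export
selectTrials <- function(trials, predicate) {
  stopifnot(is(trials, "TrialTensor"))
  expr <- substitute(predicate)
  keep <- if (is.logical(predicate <- tryCatch(predicate, error = function(e) NULL))
              && length(predicate) == dim(trials@data)[3]) {
    predicate
  } else {
    eval(expr, trials@trials, parent.frame())
  }
  keep[is.na(keep)] <- FALSE
  if (!any(keep))
    stop("empty selection for predicate: ", deparse(expr))
  message(sum(keep), " of ", length(keep), " trials selected")
  meta <- trials@trials[keep, , drop = FALSE]
  attr(meta, "roleOnsets") <- attr(trials@trials, "roleOnsets")
  rownames(meta) <- NULL
  new("TrialTensor", data = trials@data[, , keep, drop = FALSE],
      time = trials@time, fs = trials@fs, channels = trials@channels,
      trials = meta, mask = trials@mask[, , keep, drop = FALSE])
}

#' Behavioural summary of an event table
#'
#' Reaction-time mean and SD and the ratio of correct answers, overall and
#' per group (e.g. per numerical format).
#'
#' @param events event table with per-trial response, correct and rt columns.
#' @param groupBy optional character vector of metadata columns to group by.
#' @return data.frame with columns group columns (if any), n, accuracy,
#'   rtMean, rtSd.
#' @export
behavioralSummary <- function(events, groupBy = NULL) {
  events <- as.data.frame(events)
  if (is.null(events$response) || !nrow(events)) stop("no responses present")
  tr <- events[!duplicated(events$trial), , drop = FALSE]
  summarise <- function(d) data.frame(
    n = nrow(d), accuracy = mean(d$correct),
    rtMean = mean(d$rt), rtSd = if (nrow(d) > 1) sd(d$rt) else 0)
  if (is.null(groupBy)) return(summarise(tr))
  groups <- split(tr, tr[, groupBy, drop = FALSE], drop = TRUE)
  out <- do.call(rbind, lapply(names(groups), function(g) {
    cbind(stats::setNames(as.data.frame(strsplit(g, "\\.")[[1]][seq_along(groupBy)],
                                        stringsAsFactors = FALSE), groupBy),
          summarise(groups[[g]]))
  }))
  rownames(out) <- NULL
  out
}
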