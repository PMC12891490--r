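# Readers and writers: plain float32 binary + JSON sidecar (primary
# container), EDF, BrainVision, and the TSV/JSON side tables.

## ---- plain binary container -----------------------------------------------

#' Read/write the plain binary recording container
#'
#' The primary on-disk container: column-major float32 little-endian samples
#' in `<path>.bin`, axis and channel metadata in `<path>.json`, and (only if
#' any sample is masked) a uint8 mask in `<path>.mask.bin`.
#'
#' @param rec a [Recording-class].
#' @param path base path without extension.
#' @return `writeRecording` returns `path` invisibly; `readRecording`
#'   returns the [Recording-class].
#' @export
writeRecording <- function(rec, path) {
  stopifnot(is(rec, "Recording"))
  con <- file(paste0(path, ".bin"), "wb")
  writeBin(as.vector(rec@signal), con, size = 4L, endian = "little")
  close(con)
  hasMask <- any(rec@mask)
  if (hasMask) {
    con <- file(paste0(path, ".mask.bin"), "wb")
    writeBin(as.integer(rec@mask), con, size = 1L, endian = "little")
    close(con)
  }
  meta <- list(format = "ieegnet-recording", dtype = "float32",
               byte_order = "little", n_samples = nrow(rec@signal),
               n_channels = ncol(rec@signal), fs = rec@fs,
               has_mask = hasMask, channels = rec@channels)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows", na = "null")
  invisible(path)
}

#' @rdname writeRecording
#' @export
readRecording <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- meta$n_samples * meta$n_channels
  con <- file(paste0(path, ".bin"), "rb")
  x <- readBin(con, "numeric", n = n, size = 4L, endian = "little")
  close(con)
  sig <- matrix(x, meta$n_samples, meta$n_channels)
  mask <- NULL
  if (isTRUE(meta$has_mask)) {
    con <- file(paste0(path, ".mask.bin"), "rb")
    m <- readBin(con, "integer", n = n, size = 1L, signed = FALSE,
                 endian = "little")
    close(con)
    mask <- matrix(m > 0L, meta$n_samples, meta$n_channels)
  }
  chans <- as.data.frame(meta$channels)
  chans$contact <- suppressWarnings(as.integer(chans$contact))
  Recording(sig, meta$fs, chans, mask)
}

## ---- EDF ------------------------------------------------------------------

edfPad <- function(x, width)
  substr(formatC(as.character(x), width = width, flag = "-"), 1, width)

# 8-character EDF numeric field; returns the string and the value it parses
# back to (used for the physical min/max so scaling matches the header).
edfNum8 <- function(x) {
  s <- vapply(x, function(v) {
    for (d in 7:1) {
      c0 <- formatC(v, digits = d, format = "g", width = -1)
      if (nchar(c0) <= 8) return(c0)
    }
    substr(formatC(v, format = "g"), 1, 8)
  }, "")
  list(text = s, value = as.numeric(s))
}

#' Read/write continuous EDF recordings
#'
#' Minimal European Data Format support for continuous multichannel
#' recordings: 16-bit samples with per-signal physical/digital scaling, one
#' data record per second. `writeEDF` truncates the recording to whole
#' seconds (EDF stores whole data records); amplitudes are quantized to the
#' per-channel physical range.
#'
#' @param rec a [Recording-class] (the mask is not stored in EDF).
#' @param path file path (.edf).
#' @return `readEDF` returns a [Recording-class].
#' @export
writeEDF <- function(rec, path) {
  stopifnot(is(rec, "Recording"))
  fs <- rec@fs
  if (abs(fs - round(fs)) > 1e-9) stop("EDF export needs an integer sampling rate")
  nRec <- floor(nrow(rec@signal) / fs)
  if (nRec < 1) stop("recording shorter than one EDF data record (1 s)")
  nCh <- ncol(rec@signal)
  sig <- rec@signal[seq_len(nRec * fs), , drop = FALSE]
  pmin <- apply(sig, 2, min); pmax <- apply(sig, 2, max)
  flat <- pmax - pmin < 1e-9
  pmax[flat] <- pmax[flat] + 1
  # widen slightly so the 8-character header fields still bracket the data
  rng <- pmax - pmin
  pminF <- edfNum8(pmin - 0.001 * rng)
  pmaxF <- edfNum8(pmax + 0.001 * rng)
  pmin <- pminF$value; pmax <- pmaxF$value
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edfPad("0", 8), edfPad("X X X X", 80), edfPad("Startdate X X X X", 80),
    edfPad("01.01.00", 8), edfPad("00.00.00", 8),
    edfPad(256 * (1 + nCh), 8), edfPad("", 44),
    edfPad(nRec, 8), edfPad(1, 8), edfPad(nCh, 4))
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, width)
    writeChar(paste0(vapply(vals, edfPad, "", width = width), collapse = ""),
              con, eos = NULL)
  field(substr(rec@channels$name, 1, 16), 16)
  field(rep("", nCh), 80)
  field(rep("uV", nCh), 8)
  field(pminF$text, 8)
  field(pmaxF$text, 8)
  field(rep(dmin, nCh), 8)
  field(rep(dmax, nCh), 8)
  field(rep("", nCh), 80)
  field(rep(fs, nCh), 8)
  field(rep("", nCh), 32)
  for (r in seq_len(nRec)) {
    rows <- ((r - 1L) * fs + 1L):(r * fs)
    for (j in seq_len(nCh)) {
      dig <- round((sig[rows, j] - pmin[j]) / (pmax[j] - pmin[j]) *
                     (dmax - dmin) + dmin)
      writeBin(as.integer(dig), con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' @rdname writeEDF
#' @export
readEDF <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8); rd(44)
  nRec <- as.integer(rd(8))
  recDur <- as.numeric(rd(8))
  nCh <- as.integer(rd(4))
  rdv <- function(w) vapply(seq_len(nCh), function(i) rd(w), "")
  labels <- rdv(16); rdv(80); rdv(8)
  pmin <- as.numeric(rdv(8)); pmax <- as.numeric(rdv(8))
  dmin <- as.numeric(rdv(8)); dmax <- as.numeric(rdv(8))
  rdv(80)
  spr <- as.integer(rdv(8))
  rdv(32)
  if (length(unique(spr)) != 1L)
    stop("mixed per-signal sampling rates are not supported")
  sig <- matrix(0, nRec * spr[1], nCh)
  for (r in seq_len(nRec)) {
    rows <- ((r - 1L) * spr[1] + 1L):(r * spr[1])
    for (j in seq_len(nCh)) {
      dig <- readBin(con, "integer", n = spr[j], size = 2L, endian = "little")
      sig[rows, j] <- (dig - dmin[j]) / (dmax[j] - dmin[j]) *
        (pmax[j] - pmin[j]) + pmin[j]
    }
  }
  Recording(sig, spr[1] / recDur, data.frame(name = labels))
}

## ---- BrainVision ----------------------------------------------------------

parseVhdrSections <- function(lines) {
  out <- list(); sec <- ""
  for (ln in lines) {
    ln <- sub(";.*$", "", ln)
    if (grepl("^\\s*\\[", ln)) {
      sec <- gsub("\\[|\\]", "", trimws(ln))
      out[[sec]] <- character()
    } else if (grepl("=", ln, fixed = TRUE) && nzchar(sec)) {
      out[[sec]] <- c(out[[sec]], trimws(ln))
    }
  }
  lapply(out, function(kv) {
    keys <- sub("=.*$", "", kv)
    vals <- sub("^[^=]*=", "", kv)
    stats::setNames(as.list(vals), keys)
  })
}

#' Read a BrainVision recording
#'
#' Reads the .vhdr/.eeg/.vmrk triplet (multiplexed binary, IEEE_FLOAT_32 or
#' INT_16 with per-channel resolution). Markers are returned in the
#' `markers` attribute as a data.frame (type, description, time in s).
#'
#' @param vhdrPath path to the .vhdr header file.
#' @return a [Recording-class] with a `markers` attribute.
#' @export
readBrainVision <- function(vhdrPath) {
  sec <- parseVhdrSections(readLines(vhdrPath, warn = FALSE))
  ci <- sec[["Common Infos"]]
  bi <- sec[["Binary Infos"]]
  nCh <- as.integer(ci$NumberOfChannels)
  fs <- 1e6 / as.numeric(ci$SamplingInterval)
  if (!is.null(ci$DataOrientation) &&
      toupper(ci$DataOrientation) != "MULTIPLEXED")
    stop("only MULTIPLEXED BrainVision data are supported")
  chinfo <- sec[["Channel Infos"]]
  parts <- lapply(chinfo, function(v) strsplit(v, ",", fixed = TRUE)[[1]])
  names_ <- vapply(parts, `[`, "", 1)
  resol <- vapply(parts, function(p)
    if (length(p) >= 3 && nzchar(p[3])) as.numeric(p[3]) else 1, 0)
  dataFile <- file.path(dirname(vhdrPath), ci$DataFile)
  fmt <- toupper(if (is.null(bi$BinaryFormat)) "IEEE_FLOAT_32" else bi$BinaryFormat)
  sz <- file.size(dataFile)
  con <- file(dataFile, "rb")
  if (fmt == "IEEE_FLOAT_32") {
    raw <- readBin(con, "numeric", n = sz / 4, size = 4L, endian = "little")
  } else if (fmt == "INT_16") {
    raw <- readBin(con, "integer", n = sz / 2, size = 2L, endian = "little")
  } else stop("unsupported BinaryFormat: ", fmt)
  close(con)
  nSamp <- length(raw) %/% nCh
  sig <- t(matrix(raw[seq_len(nSamp * nCh)], nCh, nSamp))
  sig <- sweep(sig, 2, resol, "*")
  rec <- Recording(sig, fs, data.frame(name = names_))
  vmrk <- file.path(dirname(vhdrPath), ci$MarkerFile)
  if (!is.null(ci$MarkerFile) && file.exists(vmrk)) {
    ms <- parseVhdrSections(readLines(vmrk, warn = FALSE))[["Marker Infos"]]
    if (length(ms)) {
      mp <- lapply(ms, function(v) strsplit(v, ",", fixed = TRUE)[[1]])
      attr(rec, "markers") <- data.frame(
        type = vapply(mp, `[`, "", 1),
        description = vapply(mp, `[`, "", 2),
        time = (as.numeric(vapply(mp, `[`, "", 3)) - 1) / fs)
    }
  }
  rec
}

#' @rdname readBrainVision
#' @param rec a [Recording-class].
#' @param basePath base path without extension; writes `<basePath>.vhdr`,
#'   `.eeg` and `.vmrk`.
#' @param markers optional data.frame (type, description, time in s).
#' @export
writeBrainVision <- function(rec, basePath, markers = NULL) {
  stopifnot(is(rec, "Recording"))
  base <- basename(basePath)
  hdr <- c("Brain Vision Data Exchange Header File Version 1.0",
           "[Common Infos]",
           paste0("DataFile=", base, ".eeg"),
           paste0("MarkerFile=", base, ".vmrk"),
           "DataFormat=BINARY",
           "DataOrientation=MULTIPLEXED",
           paste0("NumberOfChannels=", ncol(rec@signal)),
           paste0("SamplingInterval=", format(1e6 / rec@fs, digits = 12)),
           "[Binary Infos]",
           "BinaryFormat=IEEE_FLOAT_32",
           "[Channel Infos]",
           paste0("Ch", seq_len(ncol(rec@signal)), "=",
                  rec@channels$name, ",,1,uV"))
  writeLines(hdr, paste0(basePath, ".vhdr"))
  con <- file(paste0(basePath, ".eeg"), "wb")
  writeBin(as.vector(t(rec@signal)), con, size = 4L, endian = "little")
  close(con)
  mk <- c("Brain Vision Data Exchange Marker File, Version 1.0",
          "[Common Infos]", paste0("DataFile=", base, ".eeg"),
          "[Marker Infos]")
  if (!is.null(markers) && nrow(markers))
    mk <- c(mk, paste0("Mk", seq_len(nrow(markers)), "=", markers$type, ",",
                       markers$description, ",",
                       round(markers$time * rec@fs) + 1L, ",1,0"))
  writeLines(mk, paste0(basePath, ".vmrk"))
  invisible(basePath)
}

## ---- TSV and JSON side tables ---------------------------------------------

#' Read/write the TSV side tables
#'
#' UTF-8, tab-separated, dot-decimal dialect. Event tables need trial, role
#' and onset columns; channel maps need subject, channel and roi; montage
#' tables (contact level) need subject, shank, contact, name and optionally
#' roi and flags; spike tables need channel and time.
#'
#' @param path file path.
#' @param x the table to write.
#' @return the data.frame (readers) or `path` invisibly (writers).
#' @export
readEvents <- function(path) {
  ev <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("trial", "role", "onset")
  if (!all(need %in% names(ev)))
    stop("event table must have columns: ", paste(need, collapse = ", "))
  if (!is.null(ev$rt) && any(ev$rt < 0, na.rm = TRUE))
    stop("negative reaction times in event table")
  ev
}

#' @rdname readEvents
#' @export
writeEvents <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname readEvents
#' @export
readChannelMap <- function(path) {
  cm <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("subject", "channel", "roi")
  if (!all(need %in% names(cm)))
    stop("channel map must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(cm[, c("subject", "channel")]))
    stop("each bipolar channel maps to at most one ROI")
  cm
}

#' @rdname readEvents
#' @export
writeChannelMap <- function(x, path) writeEvents(x, path)

#' @rdname readEvents
#' @export
readMontageTable <- function(path) {
  mt <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("subject", "shank", "contact", "name")
  if (!all(need %in% names(mt)))
    stop("montage table must have columns: ", paste(need, collapse = ", "))
  if (is.null(mt$roi)) mt$roi <- NA_character_
  if (is.null(mt$flags)) mt$flags <- NA_character_
  dup <- duplicated(mt[, c("subject", "shank", "contact")])
  if (any(dup)) stop("contacts on one shank must have distinct indices")
  mt
}

#' @rdname readEvents
#' @export
readSpikes <- function(path) {
  sp <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("channel", "time") %in% names(sp)))
    stop("spike table must have columns channel, time")
  sp
}

#' Read/write ground truth as JSON
#'
#' @param gt a [GroundTruth-class].
#' @param path file path (.json).
#' @return `readGroundTruth` returns the [GroundTruth-class].
#' @export
writeGroundTruth <- function(gt, path) {
  stopifnot(is(gt, "GroundTruth"))
  jsonlite::write_json(
    list(bursts = gt@bursts, couplings = gt@couplings, noise = gt@noise,
         erp = gt@erp, spike_rate = gt@spikeRate),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows", na = "null")
  invisible(path)
}

#' @rdname writeGroundTruth
#' @export
readGroundTruth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  asDf <- function(d, proto) if (length(d)) as.data.frame(d) else proto
  groundTruth(bursts = asDf(x$bursts, burstSpec()[0, ]),
              couplings = asDf(x$couplings, couplingSpec()[0, ]),
              noise = x$noise,
              erp = asDf(x$erp, data.frame(roi = character(),
                                           amplitude = numeric(),
                                           latency = numeric(),
                                           width = numeric())),
              spikeRate = x$spike_rate)
}

#' Persist a trial tensor in the plain binary container
#'
#' Same container as [writeRecording()]: float32 data, JSON sidecar with the
#' axis vectors and metadata tables, uint8 mask when needed.
#'
#' @param trials a [TrialTensor-class].
#' @param path base path without extension.
#' @return `readTrialTensor` returns the [TrialTensor-class].
#' @export
writeTrialTensor <- function(trials, path) {
  stopifnot(is(trials, "TrialTensor"))
  con <- file(paste0(path, ".bin"), "wb")
  writeBin(as.vector(trials@data), con, size = 4L, endian = "little")
  close(con)
  hasMask <- any(trials@mask)
  if (hasMask) {
    con <- file(paste0(path, ".mask.bin"), "wb")
    writeBin(as.integer(trials@mask), con, size = 1L, endian = "little")
    close(con)
  }
  meta <- list(format = "ieegnet-trialtensor", dtype = "float32",
               byte_order = "little", dims = dim(trials@data),
               time = trials@time, fs = trials@fs, has_mask = hasMask,
               channels = trials@channels, trials = trials@trials,
               role_onsets = as.list(attr(trials@trials, "roleOnsets")))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows", na = "null")
  invisible(path)
}

#' @rdname writeTrialTensor
#' @export
readTrialTensor <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  d <- as.integer(meta$dims)
  con <- file(paste0(path, ".bin"), "rb")
  x <- readBin(con, "numeric", n = prod(d), size = 4L, endian = "little")
  close(con)
  msk <- array(FALSE, d)
  if (isTRUE(meta$has_mask)) {
    con <- file(paste0(path, ".mask.bin"), "rb")
    m <- readBin(con, "integer", n = prod(d), size = 1L, signed = FALSE,
                 endian = "little")
    close(con)
    msk <- array(m > 0L, d)
  }
  meta$trials <- as.data.frame(meta$trials)
  if (length(meta$role_onsets))
    attr(meta$trials, "roleOnsets") <- unlist(meta$role_onsets)
  new("TrialTensor", data = array(x, d), time = meta$time, fs = meta$fs,
      channels = normalizeChannelTable(as.data.frame(meta$channels)),
      trials = meta$trials, mask = msk)
}
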