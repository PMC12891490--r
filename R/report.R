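# Network-state snapshots and the end-to-end pipeline runner.

#' Network-state snapshots at connectivity time points
#'
#' For each stimulus period and each detected connectivity time point
#' (onset, peak, offset), builds a snapshot of the network: node values are
#' the per-ROI normalized high-gamma activity at that time, edge values the
#' per-ROI-pair normalized PLV. Values are scaled to the 1st-99th percentile
#' of all ROI x time (respectively pair x time) values inside `window` and
#' clipped to [0, 1]; a degenerate percentile range maps all values to 0
#' with a warning. Scaling is order-preserving.
#'
#' @param hgbRoi matrix time x ROI of ROI-level high-gamma series (%), with
#'   column names.
#' @param times time axis (s) shared by `hgbRoi` and `plvRoi`.
#' @param plvRoi matrix time x ROI-pair of ROI-pair PLV series (%), column
#'   names "roiA|roiB".
#' @param timepoints data.frame (period, onset, peak, offset) from
#'   [detectTimepoints()].
#' @param band band label attached to the states.
#' @param window percentile-scaling window (s), default c(0, 6).
#' @return list(nodes, edges): data.frames with columns period, point,
#'   time, band, roi (or roiA/roiB), value, scaled.
#' @export
networkStates <- function(hgbRoi, times, plvRoi, timepoints, band = "delta",
                          window = c(0, 6)) {
  wIdx <- which(times >= window[1] - 1e-9 & times <= window[2] + 1e-9)
  scaler <- function(vals) {
    qs <- stats::quantile(vals, c(0.01, 0.99), na.rm = TRUE, names = FALSE)
    if (diff(qs) <= 1e-12) {
      warning("degenerate percentile range; all values scaled to 0")
      function(v) rep(0, length(v))
    } else function(v) pmin(1, pmax(0, (v - qs[1]) / (qs[2] - qs[1])))
  }
  nodeScale <- scaler(hgbRoi[wIdx, , drop = FALSE])
  edgeScale <- scaler(plvRoi[wIdx, , drop = FALSE])
  nodes <- list(); edges <- list()
  for (r in seq_len(nrow(timepoints))) {
    for (pt in c("onset", "peak", "offset")) {
      t0 <- timepoints[[pt]][r]
      if (is.na(t0)) {
        warning("missing ", pt, " for period ", timepoints$period[r],
                "; state skipped")
        next
      }
      ti <- which.min(abs(times - t0))
      nv <- hgbRoi[ti, ]
      ev <- plvRoi[ti, ]
      nodes[[length(nodes) + 1L]] <- data.frame(
        period = timepoints$period[r], point = pt, time = times[ti],
        band = band, roi = colnames(hgbRoi), value = as.numeric(nv),
        scaled = nodeScale(as.numeric(nv)))
      pr <- do.call(rbind, strsplit(colnames(plvRoi), "|", fixed = TRUE))
      edges[[length(edges) + 1L]] <- data.frame(
        period = timepoints$period[r], point = pt, time = times[ti],
        band = band, roiA = pr[, 1], roiB = pr[, 2],
        value = as.numeric(ev), scaled = edgeScale(as.numeric(ev)))
    }
  }
  list(nodes = if (length(nodes)) do.call(rbind, nodes) else NULL,
       edges = if (length(edges)) do.call(rbind, edges) else NULL)
}

pipelineDefaults <- function() {
  list(
    seed = 1L,
    fs = 512,
    n_trials = 40L,
    n_subjects = 2L,
    rois = c("IPS", "pITG", "MOG", "SPL"),
    channels_per_roi = 2L,
    extraction_window = c(-2, 9),
    crop_window = c(-1, 6),
    baseline = c(-1, -0.25),
    hop_samples = 16L,
    win_s = 0.5,
    n_tapers = 2L,
    nw = 1.5,
    fmax_hz = 120,
    df_hz = 2,
    hgb_band = c(52, 120),
    alpha_mask = 0.001,
    alpha_duration = 0.05,
    alpha_plv = 0.05,
    fdr_method = "bh",
    hgb_threshold = 200,
    plv_threshold = 300,
    n_top_pairs = 15L,
    bands = c("delta", "theta"),
    correct_only = TRUE)
}

validatePipelineConfig <- function(config) {
  defaults <- pipelineDefaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  if (!all(cfg$bands %in% c("delta", "theta", "alpha")))
    stop("config error: bands must be named low-frequency bands")
  if (!cfg$fdr_method %in% c("bh", "by"))
    stop("config error: fdr_method must be bh or by")
  cfg
}

#' Run the full synthetic-session pipeline
#'
#' Simulates the configured sessions, preprocesses, epochs, computes the
#' normalized spectrograms, high-gamma profiles, indicators, latency
#' ordering, PLV connectivity (delta/theta), time points and network
#' states, and writes tidy TSV tables plus a JSON manifest of all
#' parameters to `outDir`. Deterministic for a fixed seed.
#'
#' @param config a named list, or a path to a JSON/YAML config file; keys
#'   default to `pipelineDefaults()` and unknown keys fail fast.
#' @param seed integer seed overriding the config's.
#' @param outDir output directory (created if needed); NULL writes nothing.
#' @param truth optional [GroundTruth-class]; defaults to a representative
#'   activation-plus-coupling scenario over the configured ROIs.
#' @return (invisibly) a list with the main result tables.
#' @export
runPipeline <- function(config = list(), seed = NULL, outDir = NULL,
                        truth = NULL) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  cfg <- validatePipelineConfig(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  rois <- cfg$rois
  if (is.null(truth)) {
    lat <- seq(0.15, by = 0.15, length.out = length(rois))
    truth <- groundTruth(
      bursts = burstSpec(roi = rois, role = "N1", latency = lat,
                         duration = 0.3, amplitude = 3),
      couplings = couplingSpec(roiA = rois[1], roiB = rois[2],
                               band = c(3, 7), plv = 0.8, role = "N1",
                               window = c(0.1, 0.9)),
      erp = data.frame(roi = rois[1], amplitude = 15, latency = 0.08,
                       width = 0.35))
  }
  badRoi <- setdiff(unique(c(truth@bursts$roi, truth@couplings$roi_a,
                             truth@couplings$roi_b)), rois)
  if (length(badRoi))
    stop("config error: unknown ROI label(s): ", paste(badRoi, collapse = ", "))

  sched <- taskSchedule(nTrials = cfg$n_trials)
  hgbList <- list(); trialsList <- list(); plvList <- list()
  events1 <- NULL
  for (s in seq_len(cfg$n_subjects)) {
    montage <- data.frame(
      subject = sprintf("s%02d", s),
      channel = paste0(rep(rois, each = cfg$channels_per_roi), "_",
                       seq_len(cfg$channels_per_roi)),
      roi = rep(rois, each = cfg$channels_per_roi))
    sim <- simulateSubject(sched, truth, montage, fs = cfg$fs,
                           seed = cfg$seed + 101L * s)
    rec <- filterChain(sim@recording)
    if (nrow(sim@spikes)) rec <- applySpikeMask(rec, sim@spikes)
    tt <- extractTrials(rec, sim@events, cfg$extraction_window)
    if (cfg$correct_only) tt <- suppressMessages(selectTrials(tt, correct))
    ttc <- cropTrials(tt, cfg$crop_window)
    spec <- multitaperSpectrogram(ttc, winS = cfg$win_s,
                                  hopSamples = cfg$hop_samples,
                                  nTapers = cfg$n_tapers, nw = cfg$nw,
                                  fmax = cfg$fmax_hz, dfHz = cfg$df_hz)
    nspec <- baselineNormalize(spec, cfg$baseline)
    hgbList[[s]] <- extractHgb(nspec, cfg$hgb_band)
    trialsList[[s]] <- tt
    plvRaw <- plvConnectivity(tt, bands = bandSpec(120)[1:2, ],
                              cropWindow = cfg$crop_window,
                              hopSamples = cfg$hop_samples, winS = cfg$win_s)
    plvList[[s]] <- normalizePlv(plvRaw, cfg$baseline)
    if (s == 1L) events1 <- sim@events
  }
  pooled <- combineHgb(hgbList)
  roiTabs <- lapply(rois, function(r)
    roiHgb(pooled, roi = r, baseline = cfg$baseline,
           alpha = cfg$alpha_mask, fdrMethod = cfg$fdr_method))
  names(roiTabs) <- rois
  roiSeries <- sapply(roiTabs, `[[`, "hgb")
  hgbTab <- do.call(rbind, lapply(rois, function(r)
    cbind(roi = r, roiTabs[[r]])))
  indic <- do.call(rbind, lapply(hgbList, function(h)
    hgbIndicators(h, baseline = cfg$baseline, alpha = cfg$alpha_duration,
                  fdrMethod = cfg$fdr_method)))
  ordering <- latencyOrdering(pooled, threshold = cfg$hgb_threshold,
                              fdrMethod = cfg$fdr_method)
  behav <- behavioralSummary(events1)

  # pool PLV pairs across subjects
  plvAll <- poolPlvSets(plvList)
  results <- list(behavior = behav, hgb = hgbTab, indicators = indic,
                  ordering = ordering)
  relOn <- attr(trialsList[[1]]@trials, "roleOnsets")
  periods <- data.frame(name = c("N1", "N2", "N3"),
                        start = as.numeric(relOn[c("N1", "N2", "N3")]),
                        end = as.numeric(relOn[c("N1", "N2", "N3")]) + 1.05)
  for (band in cfg$bands) {
    pb <- bandAverage(plvAll, band)
    g <- globalPlv(pb, alpha = cfg$alpha_plv, fdrMethod = cfg$fdr_method)
    tp <- detectTimepoints(g$plv, g$time, periods)
    top <- topPairs(pb, period = c(periods$start[1], periods$end[1]),
                    n = cfg$n_top_pairs, threshold = cfg$plv_threshold)
    combos <- utils::combn(rois, 2)
    plvRoi <- sapply(seq_len(ncol(combos)), function(k) {
      rp <- roiPairPlv(pb, combos[1, k], combos[2, k])
      if (is.null(rp$series)) rep(NA_real_, length(pb@times)) else rp$series
    })
    colnames(plvRoi) <- paste(combos[1, ], combos[2, ], sep = "|")
    hgbRoiM <- as.matrix(roiSeries)
    states <- suppressWarnings(
      networkStates(hgbRoiM, pooled@times, plvRoi, tp, band = band))
    results[[paste0("plv_", band)]] <- g
    results[[paste0("timepoints_", band)]] <- tp
    results[[paste0("top_pairs_", band)]] <- top
    results[[paste0("states_", band)]] <- states
  }

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(x, name) if (!is.null(x) && is.data.frame(x))
      writeEvents(x, file.path(outDir, paste0(name, ".tsv")))
    wr(results$behavior, "behavior")
    wr(results$hgb, "hgb_roi")
    wr(results$indicators, "indicators")
    for (band in cfg$bands) {
      wr(results[[paste0("plv_", band)]], paste0("plv_global_", band))
      wr(results[[paste0("timepoints_", band)]], paste0("timepoints_", band))
      wr(results[[paste0("top_pairs_", band)]], paste0("top_pairs_", band))
      st <- results[[paste0("states_", band)]]
      wr(st$nodes, paste0("state_nodes_", band))
      wr(st$edges, paste0("state_edges_", band))
    }
    ordTab <- do.call(rbind, lapply(names(results$ordering), function(per)
      if (nrow(results$ordering[[per]]$ordering))
        cbind(period = per, results$ordering[[per]]$ordering) else NULL))
    wr(ordTab, "latency_ordering")
    manifest <- list(package = "ieegnet",
                     version = as.character(utils::packageVersion("ieegnet")),
                     r_version = R.version.string,
                     parameters = cfg)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(results)
}

# Concatenate the pair dimension of per-subject PLV sets on one time axis.
poolPlvSets <- function(plvList) {
  stopifnot(length(plvList) >= 1L)
  t0 <- plvList[[1]]@times
  arrs <- lapply(plvList, function(p) p@plv)
  pairs <- do.call(rbind, lapply(plvList, function(p) p@pairs))
  rownames(pairs) <- NULL
  plv <- array(NA_real_, c(length(t0), nrow(plvList[[1]]@bands), nrow(pairs)))
  k <- 0L
  for (a in arrs) {
    np <- dim(a)[3]
    plv[, , (k + 1L):(k + np)] <- a
    k <- k + np
  }
  new("PLVSet", plv = plv, times = t0, bands = plvList[[1]]@bands,
      pairs = pairs, normalized = plvList[[1]]@normalized,
      nTrials = plvList[[1]]@nTrials,
      baselineWindow = plvList[[1]]@baselineWindow)
}
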