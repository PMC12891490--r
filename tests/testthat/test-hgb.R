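# High-gamma extraction, ROI profiles, indicators, period contrasts and
# latency ordering.

test_that("high-gamma bins: 52-120 Hz minus the notched harmonics", {
  fr <- seq(0, 120, 2)
  bins <- ieegnet:::hgbBins(fr)
  expect_equal(length(bins), 32)
  expect_equal(fr[bins], setdiff(seq(52, 120, 2), c(98, 100, 102)))
})

test_that("constant in-band spectrogram yields a constant HGB series and
           per-trial extraction commutes with trial averaging", {
  vals <- array(50, c(6, 61, 2, 4))
  sp <- makeSpec(vals, times = seq(0, 0.5, 0.1), freqs = seq(0, 120, 2))
  h <- extractHgb(sp)
  expect_true(all(h@perTrial == 50))
  expect_true(all(trialAverage(h) == 50))
  # commutation on random data: mean-then-extract equals extract-then-mean
  set.seed(13)
  v2 <- array(rnorm(6 * 61 * 2 * 4), c(6, 61, 2, 4))
  sp2 <- makeSpec(v2, times = seq(0, 0.5, 0.1), freqs = seq(0, 120, 2))
  h2 <- extractHgb(sp2)
  spAvg <- makeSpec(array(apply(v2, 1:3, mean), c(6, 61, 2, 1)),
                    times = seq(0, 0.5, 0.1), freqs = seq(0, 120, 2))
  expect_equal(trialAverage(h2), extractHgb(spAvg)@perTrial[, , 1],
               tolerance = 1e-12)
  expect_error(extractHgb(makeSpec(vals, times = seq(0, 0.5, 0.1),
                                   freqs = seq(0, 120, 2),
                                   normalized = FALSE)),
               "normalized")
  expect_error(extractHgb(sp, band = c(130, 140)), "no qualifying")
})

test_that("an injected high-gamma burst is recovered at its latency and
           amplitude", {
  sim <- quickSim(nTrials = 25,
                  bursts = burstSpec("IPS", "N1", latency = 0.2,
                                     duration = 0.3, amplitude = 3),
                  seed = 31)
  tt <- cropTrials(extractTrials(sim@recording, sim@events, c(-1.3, 1.4)),
                   c(-1.05, 1.3))
  h <- extractHgb(baselineNormalize(multitaperSpectrogram(tt)))
  d <- roiHgb(h, roi = "IPS", alpha = 0.05)
  tw <- d$time >= 0 & d$time <= 1
  pk <- d$time[tw][which.max(d$hgb[tw])]
  expect_lt(abs(pk - 0.2), 16 / 512 + 1e-9)      # within one hop
  expect_gt(max(d$hgb[tw]), 200)                 # ~3 baseline SDs
  # the uninjected ROI stays near baseline
  d2 <- roiHgb(h, roi = "MOG", alpha = 0.05)
  expect_lt(max(abs(d2$hgb[tw])), 150)
})

test_that("indicators M, T, b have their closed-form values on
           constructed series", {
  times <- seq(0, 5, by = 16 / 512)
  nT <- length(times)
  # flat zero series
  z <- makeHgb(array(0, c(nT, 1, 10)), times)
  iz <- hgbIndicators(z, interval = c(0, 5), baseline = c(0, 0.5))
  expect_equal(c(iz$M, iz$T, iz$b), c(0, 0, 0))
  # ramp 100 %/s: slope exact, M = mean(|100 t|) = 250
  ramp <- array(rep(100 * times, 10), c(nT, 1, 10))
  ir <- hgbIndicators(makeHgb(ramp, times), interval = c(0, 5),
                      baseline = c(0, 0.5))
  expect_equal(ir$b, 100, tolerance = 1e-9)
  expect_equal(ir$M, mean(abs(100 * times)), tolerance = 1e-9)
  # sustained shifted burst of ~1 s is recovered by T within [0.8, 1.2]
  set.seed(14)
  times2 <- seq(-1, 2, by = 16 / 512)
  nT2 <- length(times2)
  per <- array(rnorm(nT2 * 1 * 60, sd = 100), c(nT2, 1, 60))
  on <- times2 >= 0.5 & times2 < 1.5
  per[on, 1, ] <- per[on, 1, ] + 300
  it <- hgbIndicators(makeHgb(per, times2), interval = c(0, 2),
                      baseline = c(-1, -0.25), alpha = 0.05)
  expect_gte(it$T, 0.8)
  expect_lte(it$T, 1.2)
})

test_that("period means use [onset, onset + 1.05) windows per role", {
  times <- seq(-1, 6, by = 16 / 512)
  nT <- length(times)
  per <- array(40, c(nT, 2, 5))
  # add activity only in the N2 period on channel 1
  n2 <- times >= 2.1 & times < 3.15
  per[n2, 1, ] <- per[n2, 1, ] + 100
  h <- makeHgb(per, times)
  m <- periodMeans(h)
  expect_equal(unname(m[2, ]), rep(40, 5))             # untouched channel
  expect_equal(unname(m[1, c("N1", "O1", "O2", "N3")]), rep(40, 4))
  expect_equal(unname(m[1, "N2"]), 140)
  expect_error(periodMeans(h, roles = "XX"), "absent")
})

test_that("period comparison matches the exact binomial sign-test oracle", {
  set.seed(15)
  nCh <- 20
  means <- cbind(N1 = rnorm(nCh), O1 = rnorm(nCh), N2 = 0, O2 = rnorm(nCh),
                 N3 = rnorm(nCh))
  means[, "N2"] <- means[, "N1"] + abs(rnorm(nCh)) + 0.1   # all increase
  chans <- data.frame(name = paste0("ch", 1:nCh), subject = "s01",
                      roi = "IPS")
  out <- comparePeriods(means, chans, pairs = list(c("N1", "N2")))
  expect_equal(out$p, 2 * 0.5^20, tolerance = 1e-12)
  expect_equal(out$direction, "increase")
  # identical means: p = 1
  m2 <- means; m2[, "N2"] <- m2[, "N1"]
  out2 <- comparePeriods(m2, chans, pairs = list(c("N1", "N2")))
  expect_true(is.na(out2$p) || out2$p == 1)
})

test_that("latency ordering recovers staggered injections and applies the
           activation threshold", {
  # constructed ROI series with known peak latencies and amplitudes
  times <- seq(-1, 6, by = 16 / 512)
  nT <- length(times)
  lat <- c(IPS = 0.15, MOG = 0.40, SPL = 0.62)
  amp <- c(IPS = 320, MOG = 260, SPL = 120)    # SPL below the 200% threshold
  rois <- names(lat)
  nPer <- 8                                    # channels per ROI
  per <- array(0, c(nT, 3 * nPer, 8))
  set.seed(16)
  for (k in seq_along(rois)) {
    for (j in seq_len(nPer)) {
      ch <- (k - 1) * nPer + j
      latCh <- lat[k] + rnorm(1, sd = 0.015)   # small per-channel jitter
      shape <- amp[k] * exp(-(times - latCh)^2 / (2 * 0.1^2))
      per[, ch, ] <- shape + rnorm(nT * 8, sd = 10)
    }
  }
  h <- makeHgb(per, times, rois = rep(rois, each = nPer))
  ord <- latencyOrdering(h, periods = "N1")
  expect_equal(ord$N1$ordering$roi, c("IPS", "MOG"))   # SPL excluded
  expect_lt(max(abs(ord$N1$ordering$latency - lat[ord$N1$ordering$roi])),
            2 * 16 / 512 + 1e-9)
  # pairwise latency-difference test is significant for distinct latencies
  expect_true(ord$N1$pairwise$sig[1])
  # identical injected latencies: non-significant
  per2 <- per
  per2[, nPer + seq_len(nPer), ] <- per[, seq_len(nPer), ] +
    rnorm(nT * nPer * 8, sd = 10)
  h2 <- makeHgb(per2, times, rois = rep(rois, each = nPer))
  ord2 <- latencyOrdering(h2, periods = "N1")
  expect_false(ord2$N1$pairwise$sig[1])
  # all sub-threshold: empty ordering with a warning
  expect_warning(o3 <- latencyOrdering(makeHgb(per / 10, times,
                                               rois = rep(rois, each = nPer)),
                                       periods = "N1"), "threshold")
  expect_equal(nrow(o3$N1$ordering), 0)
})

test_that("condition contrasts flag the manipulated ROI only", {
  times <- seq(-1, 6, by = 16 / 512)
  nT <- length(times)
  nCh <- 16; nTr <- 40
  set.seed(17)
  per <- array(rnorm(nT * nCh * nTr, sd = 50), c(nT, nCh, nTr))
  trials <- data.frame(trial = 1:nTr,
                       format = rep(c("arabic", "dice"), 20),
                       difficulty = "difficult",
                       op1 = rep(c("+", "-"), each = 20),
                       op2 = "+",
                       decade_role = rep(c("N2", "N3"), 20),
                       correct = TRUE, rt = 1)
  # decade crossing adds power in the crossing operand period, ROI "IPS"
  # (channels 1:6) only
  for (tr in 1:nTr) {
    win <- if (trials$decade_role[tr] == "N2") times >= 2.1 & times < 3.15
           else times >= 4.2 & times < 5.25
    per[win, 1:8, tr] <- per[win, 1:8, tr] + 150
  }
  h <- makeHgb(per, times, rois = rep(c("IPS", "MOG"), each = 8),
               trials = trials)
  out <- conditionContrasts(h, "decade_crossing")
  expect_true(out$tests$sig[out$tests$roi == "IPS"])
  expect_false(out$tests$sig[out$tests$roi == "MOG"])
  expect_equal(out$tests$direction[out$tests$roi == "IPS"], "increase")
  # format similarity: identical trials relabelled -> CC ~ 1
  fmt <- conditionContrasts(h, "format")
  expect_gt(fmt$cc$meanCC[fmt$cc$roi == "MOG"], -1)  # defined
  hNoise0 <- makeHgb(array(rep(rnorm(nT * nCh), nTr), c(nT, nCh, nTr)),
                     times, rois = rep(c("IPS", "MOG"), each = 8),
                     trials = trials)
  fmt0 <- conditionContrasts(hNoise0, "format")
  expect_equal(fmt0$cc$meanCC, c(1, 1), tolerance = 1e-9)
})
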