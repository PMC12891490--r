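# Synthetic-session generator: event schedule, pink noise, von Mises
# coupling calibration, and determinism.

test_that("event schedule arithmetic: counts, spacing and jitter", {
  sched <- taskSchedule(nTrials = 10)
  ev <- generateEvents(sched, seed = 3)
  expect_equal(nrow(ev), 10 * 7)
  # consecutive stimulus onsets within a trial spaced exactly 1.05 s
  for (tr in unique(ev$trial)) {
    on <- ev$onset[ev$trial == tr]
    expect_equal(diff(on), rep(1.05, 6), tolerance = 1e-12)
  }
  # onset(N2) - onset(N1) = 2.10 s
  d <- ev$onset[ev$role == "N2"] - ev$onset[ev$role == "N1"]
  expect_equal(d, rep(2.10, 10), tolerance = 1e-12)
  # fixation (inter-trial gap minus response + feedback) within its range
  n1 <- ev$onset[ev$role == "N1"]
  res <- ev$onset[ev$role == "RESULT"]
  rt <- ev$rt[!duplicated(ev$trial)]
  fix <- n1[-1] - (res[-10] + 1.05 + rt[-10] + sched@feedbackDuration)
  expect_true(all(fix >= 1.05 - 1e-9 & fix <= 1.55 + 1e-9))
  # determinism: identical tables (including jitters) under a fixed seed
  expect_identical(ev, generateEvents(sched, seed = 3))
  expect_false(identical(ev$onset, generateEvents(sched, seed = 4)$onset))
  expect_error(taskSchedule(stimulusDuration = -1), "non-positive")
})

test_that("pink noise has the requested spectral slope and RMS", {
  # white: flat spectrum
  w <- makePinkNoise(2^14, exponent = 0, rms = 1, seed = 1)
  expect_equal(sqrt(mean(w^2)), 1, tolerance = 1e-12)
  # 1/f: log-log PSD slope -1 +- 0.1 (Welch-style averaged periodogram)
  x <- makePinkNoise(2^16, exponent = 1, rms = 5, seed = 2)
  expect_equal(sqrt(mean(x^2)), 5, tolerance = 1e-12)
  nseg <- 64L; L <- 1024L
  acc <- 0
  for (s in seq_len(nseg)) {
    seg <- x[((s - 1) * L + 1):(s * L)]
    acc <- acc + Mod(stats::fft(seg))^2
  }
  psd <- acc[2:(L / 2)] / nseg
  fr <- (1:(L / 2 - 1)) / L
  fit <- lm(log10(psd) ~ log10(fr))
  expect_equal(unname(coef(fit)[2]), -1, tolerance = 0.1)
  # determinism
  expect_identical(x, makePinkNoise(2^16, exponent = 1, rms = 5, seed = 2))
})

test_that("phase-coupling injection matches its von Mises calibration", {
  win <- cbind(seq(1, by = 2, length.out = 200), seq(1.8, by = 2, length.out = 200))
  n <- ceiling((max(win) + 1) * 512)
  # target 1: constant phase difference equal to the lag
  inj <- injectPhaseCoupling(numeric(n), numeric(n), 512, c(3, 7),
                             targetPlv = 1, lag = 0.7, windows = win, seed = 1)
  expect_equal(inj$phaseDiff, rep(0.7, 200), tolerance = 1e-12)
  # target 0.6 at N = 200: sample resultant within +-0.07 of the target
  # (95% Monte-Carlo interval of the von Mises resultant estimator)
  inj6 <- injectPhaseCoupling(numeric(n), numeric(n), 512, c(3, 7),
                              targetPlv = 0.6, windows = win, seed = 2)
  r <- Mod(mean(exp(1i * inj6$phaseDiff)))
  expect_lt(abs(r - 0.6), 0.07)
  # target 0: uniform phases; mean resultant over reps ~ sqrt(pi)/(2 sqrt(N))
  set.seed(3)
  r0 <- replicate(500, Mod(mean(exp(1i * ieegnet:::rVonMises(100, 0)))))
  expect_lt(abs(mean(r0) - sqrt(pi) / (2 * sqrt(100))), 0.008)
  expect_error(injectPhaseCoupling(numeric(10), numeric(10), 512, c(3, 7),
                                   targetPlv = 1.5, windows = win),
               "\\[0, 1\\]")
  expect_error(injectPhaseCoupling(numeric(10), numeric(10), 512, c(250, 300),
                                   targetPlv = 0.5, windows = win),
               "Nyquist")
})

test_that("coupled channels reach near-unity raw PLV at the window center", {
  rois <- c("IPS", "MOG")
  sim <- quickSim(nTrials = 30, rois = rois, bursts = burstSpec()[0, ],
                  couplings = couplingSpec(roiA = "IPS", roiB = "MOG",
                                           band = c(3, 7), plv = 1,
                                           lag = 0, role = "N1",
                                           window = c(0.1, 0.9),
                                           couplingAmplitude = 200),
                  seed = 11)
  tt <- extractTrials(sim@recording, sim@events, c(-1, 2))
  np <- narrowbandPhases(tt, bandSpec(120)[2, , drop = FALSE],
                         outTimes = 0.5)
  plv <- suppressWarnings(plvPair(matrix(np$phases[, 1, 1, ], 1),
                                  matrix(np$phases[, 1, 2, ], 1)))
  expect_gt(plv, 0.95)
})

test_that("burst injection follows its amplitude calibration and the
           simulator is deterministic", {
  # same background: the added component's RMS scales as the calibrated
  # gain ratio between amplitudes a and 2a
  simA <- quickSim(nTrials = 6, bursts = burstSpec("IPS", "N1", 0.2, 0.3, 1.5),
                   seed = 5)
  simB <- quickSim(nTrials = 6, bursts = burstSpec("IPS", "N1", 0.2, 0.3, 3.0),
                   seed = 5)
  sim0 <- quickSim(nTrials = 6, bursts = burstSpec()[0, ], seed = 5)
  addA <- simA@recording@signal[, 1] - sim0@recording@signal[, 1]
  addB <- simB@recording@signal[, 1] - sim0@recording@signal[, 1]
  sg <- ieegnet:::binBaselineSdDb(2L)
  expected <- sqrt((10^(3.0 * sg / 10) - 1) / (10^(1.5 * sg / 10) - 1))
  expect_equal(sqrt(mean(addB^2)) / sqrt(mean(addA^2)), expected,
               tolerance = 1e-6)
  # null injection: pure 1/f background at the configured RMS
  expect_equal(sd(sim0@recording@signal[, 2]),
               sim0@truth@noise$rms, tolerance = 0.02)
  # full determinism under a fixed seed
  sim2 <- quickSim(nTrials = 6, bursts = burstSpec()[0, ], seed = 5)
  expect_identical(sim0@recording@signal, sim2@recording@signal)
  expect_identical(sim0@events, sim2@events)
})

test_that("simulation rejects couplings to ROIs absent from the montage", {
  gt <- groundTruth(couplings = couplingSpec(roiA = "IPS", roiB = "ACC",
                                             plv = 0.5))
  expect_error(simulateSubject(taskSchedule(nTrials = 2), gt,
                               tinyMontage(c("IPS", "MOG"))),
               "configuration error.*ACC")
})

test_that("simulated epileptiform spikes are recorded and maskable", {
  sim <- quickSim(nTrials = 4, bursts = burstSpec()[0, ], spikeRate = 6,
                  seed = 9)
  expect_gt(nrow(sim@spikes), 0)
  rec <- applySpikeMask(sim@recording, sim@spikes)
  expect_gt(sum(rec@mask), 0)
  expect_identical(rec@signal, sim@recording@signal)  # masking, not zeroing
})
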