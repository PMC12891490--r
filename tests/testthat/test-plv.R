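# Phase extraction and PLV connectivity.

test_that("filter-Hilbert phases behave analytically", {
  fs <- 512
  tt <- signalTensorPlv(function(t) sin(2 * pi * 5 * t), fs)
  np <- narrowbandPhases(tt, bandSpec(120)[2, , drop = FALSE],
                         outTimes = seq(-0.5, 1.5, by = 1 / fs),
                         cropWindow = c(-0.5, 1.5))
  ph <- np$phases[, 1, 1, 1]
  # unwrapped theta phase advances 2*pi*5 rad/s within 1%
  slope <- mean(diff(unwrapPhase(ph))) * fs
  expect_equal(slope, 2 * pi * 5, tolerance = 0.01 * 2 * pi * 5)
  # cosine peak has phase 0 (mod 2pi)
  tc <- signalTensorPlv(function(t) cos(2 * pi * 5 * t), fs)
  npc <- narrowbandPhases(tc, bandSpec(120)[2, , drop = FALSE],
                          outTimes = 0.4)   # cos peaks at t = 0.4 (2 cycles)
  expect_lt(abs(npc$phases[1, 1, 1, 1]), 0.05)
  # white-noise phase marginal is uniform on [-pi, pi]
  set.seed(18)
  tw <- signalTensorPlv(function(t) rnorm(length(t)), fs, nTr = 8L)
  npw <- narrowbandPhases(tw, bandSpec(120)[2, , drop = FALSE],
                          outTimes = seq(0, 1, by = 0.25))
  ks <- suppressWarnings(stats::ks.test(as.vector(npw$phases),
                                        "punif", -pi, pi))
  expect_gt(ks$p.value, 0.01)
  expect_error(narrowbandPhases(tt, data.frame(name = "hf", f_lo = 250,
                                               f_hi = 280)), "Nyquist")
})

test_that("PLV estimator identities: unit vectors, cancellation, null level", {
  nT <- 4
  # constant phase difference -> PLV = 1 exactly
  phiM <- matrix(runif(nT * 40, -pi, pi), nT)
  plv1 <- suppressWarnings(plvPair(phiM, phiM - 1.2))
  expect_equal(plv1, rep(1, nT), tolerance = 1e-12)
  # antipodal halves cancel -> PLV = 0
  phiN <- phiM
  phiN[, seq(1, 40, 2)] <- phiM[, seq(1, 40, 2)] - pi
  expect_equal(suppressWarnings(plvPair(phiM, phiN)), rep(0, nT),
               tolerance = 1e-12)
  # uniform null at N = 100: mean over reps ~ sqrt(pi)/(2 sqrt(100))
  set.seed(19)
  r <- replicate(400, suppressWarnings(
    plvPair(matrix(runif(100, -pi, pi), 1),
            matrix(runif(100, -pi, pi), 1))))
  expect_lt(abs(mean(r) - sqrt(pi) / (2 * sqrt(100))), 0.005)
  expect_error(plvPair(phiM, phiM[, 1:10]), "same trial count")
  expect_warning(plvPair(matrix(0, 2, 5), matrix(0, 2, 5)), "fewer than 20")
})

test_that("PLV invariances: symmetry, common rotation, amplitude", {
  set.seed(20)
  phiM <- matrix(runif(200, -pi, pi), 5)
  phiN <- matrix(runif(200, -pi, pi), 5)
  a <- suppressWarnings(plvPair(phiM, phiN))
  expect_true(all(a >= 0 & a <= 1))
  expect_identical(a, suppressWarnings(plvPair(phiN, phiM)))
  expect_equal(a, suppressWarnings(plvPair(phiM + 0.8, phiN + 0.8)),
               tolerance = 1e-12)
  # amplitude independence through the filter-Hilbert path
  fs <- 512
  set.seed(21)
  tt <- signalTensorPlv(function(t) rnorm(length(t)), fs, nCh = 2L, nTr = 6L)
  tt2 <- tt
  tt2@data[, 1, ] <- 5.7 * tt2@data[, 1, ]
  np1 <- narrowbandPhases(tt, bandSpec(120)[1:2, ], outTimes = seq(0, 1, 0.25))
  np2 <- narrowbandPhases(tt2, bandSpec(120)[1:2, ], outTimes = seq(0, 1, 0.25))
  # the 0.1 Hz delta-band edge limits the filter's numerical conditioning,
  # so equality holds to ~1e-3 rad there (theta and above are ~1e-9)
  expect_equal(np1$phases, np2$phases, tolerance = 5e-3)
  expect_equal(np1$phases[, 2, , ], np2$phases[, 2, , ], tolerance = 1e-6)
})

test_that("PLV normalization contract and band averaging", {
  set.seed(22)
  nT <- 160; nB <- 2; nP <- 5
  times <- seq(-1, 4, length.out = nT)
  plv <- array(runif(nT * nB * nP, 0.1, 0.6), c(nT, nB, nP))
  p <- new("PLVSet", plv = plv, times = times,
           bands = bandSpec(120)[1:2, ],
           pairs = data.frame(subject = "s01", chA = paste0("a", 1:nP),
                              chB = paste0("b", 1:nP), roiA = "IPS",
                              roiB = c("MOG", "MOG", "SPL", "SPL", "SPL")),
           normalized = FALSE, nTrials = 100L, baselineWindow = numeric(0))
  np <- normalizePlv(p, c(-1, -0.25))
  bIdx <- which(times >= -1 & times <= -0.25)
  for (j in 1:nP) for (b in 1:nB) {
    expect_equal(mean(np@plv[bIdx, b, j]), 0, tolerance = 1e-9)
    expect_equal(sd(np@plv[bIdx, b, j]), 100, tolerance = 1e-9)
  }
  # constant raw PLV is degenerate
  pc <- p; pc@plv[] <- 0.4
  expect_error(normalizePlv(pc), "zero baseline variance")
  # single-band average is the identity; explicit range matches loop oracle
  d <- bandAverage(np, "delta")
  expect_equal(d@plv[, 1, ], np@plv[, 1, ], tolerance = 1e-12)
  both <- bandAverage(np, c(0.1, 7))
  expect_equal(both@plv[, 1, ], (np@plv[, 1, ] + np@plv[, 2, ]) / 2,
               tolerance = 1e-12)
  expect_error(bandAverage(np, "gamma"), "unknown band")
})

test_that("ROI-pair pooling needs two subjects and averages channel pairs", {
  nT <- 8
  mk <- function(subjects) {
    nP <- length(subjects)
    new("PLVSet", plv = array(rep(seq_len(nP), each = nT), c(nT, 1, nP)),
        times = seq(0, 1, length.out = nT),
        bands = data.frame(name = "delta", f_lo = 0.1, f_hi = 3),
        pairs = data.frame(subject = subjects, chA = "a", chB = "b",
                           roiA = "IPS", roiB = "MOG"),
        normalized = TRUE, nTrials = 50L, baselineWindow = c(-1, -0.25))
  }
  # one subject only: absent-connection marker
  one <- roiPairPlv(mk("s01"), "IPS", "MOG")
  expect_null(one$series)
  expect_equal(one$nSubjects, 1)
  # two subjects, one pair each: simple mean
  two <- roiPairPlv(mk(c("s01", "s02")), "IPS", "MOG")
  expect_equal(two$series, rep(1.5, nT))
  # three subjects: nested-loop mean oracle
  three <- roiPairPlv(mk(c("s01", "s02", "s03")), "IPS", "MOG")
  expect_equal(three$series, rep(mean(1:3), nT))
  expect_error(roiPairPlv(mk("s01"), "IPS", "IPS"), "distinct")
})

test_that("global PLV pools pairs with SEM and FDR-corrected significance", {
  set.seed(23)
  nT <- 161
  times <- seq(-1, 4, length.out = nT)
  nP <- 12
  plv <- array(rnorm(nT * nP), c(nT, 1, nP))
  bump <- 3 * exp(-(times - 1)^2 / (2 * 0.15^2))
  for (j in 1:nP) plv[, 1, j] <- plv[, 1, j] + bump
  p <- new("PLVSet", plv = plv, times = times,
           bands = data.frame(name = "delta", f_lo = 0.1, f_hi = 3),
           pairs = data.frame(subject = rep(c("s01", "s02"), 6),
                              chA = paste0("a", 1:nP), chB = paste0("b", 1:nP),
                              roiA = "IPS", roiB = "MOG"),
           normalized = TRUE, nTrials = 50L, baselineWindow = c(-1, -0.25))
  g <- globalPlv(p)
  expect_true(any(g$sig[times > 0.7 & times < 1.3]))
  expect_false(any(g$sig[times < -0.25]))
  # identical pairs give SEM 0
  pSame <- p
  for (j in 2:nP) pSame@plv[, 1, j] <- pSame@plv[, 1, 1]
  expect_equal(globalPlv(pSame)$sem, rep(0, nT))
})

test_that("onset/peak/offset detection matches Gaussian derivative extremes", {
  hop <- 16 / 512
  times <- seq(-1, 3, by = hop)
  c0 <- 0.5; s0 <- 0.22
  series <- 300 * exp(-(times - c0)^2 / (2 * s0^2))
  tp <- detectTimepoints(series, times,
                         data.frame(name = "N1", start = -0.2, end = 1.4))
  expect_equal(tp$peak, c0, tolerance = hop + 1e-9)
  expect_equal(tp$onset, c0 - s0, tolerance = 2 * hop + 1e-9)
  expect_equal(tp$offset, c0 + s0, tolerance = 2 * hop + 1e-9)
  expect_true(tp$onset <= tp$peak && tp$peak <= tp$offset)
  # monotone ramp: peak at the period end, offset absent
  ramp <- detectTimepoints(seq_along(times), times,
                           data.frame(name = "N1", start = 0, end = 1))
  expect_equal(ramp$peak, 1, tolerance = hop + 1e-9)
  expect_true(is.na(ramp$offset))
  # flat series: no detectable points
  flat <- detectTimepoints(rep(1, length(times)), times,
                           data.frame(name = "N1", start = 0, end = 1))
  expect_true(is.na(flat$peak))
})

test_that("top-pair ranking applies the threshold and orders by latency", {
  nT <- 81
  times <- seq(-1, 3, length.out = nT)
  mkSeries <- function(amp, lat) amp * exp(-(times - lat)^2 / (2 * 0.1^2))
  # 3 ROI pairs x 2 subjects each; staggered latencies, one sub-threshold
  specTab <- data.frame(roiA = c("IPS", "IPS", "MOG"),
                        roiB = c("MOG", "SPL", "SPL"),
                        amp = c(500, 400, 250), lat = c(0.2, 0.5, 0.1))
  pairs <- do.call(rbind, lapply(1:2, function(s)
    transform(specTab, subject = sprintf("s%02d", s))))
  plv <- array(0, c(nT, 1, nrow(pairs)))
  for (j in seq_len(nrow(pairs)))
    plv[, 1, j] <- mkSeries(pairs$amp[j], pairs$lat[j])
  p <- new("PLVSet", plv = plv, times = times,
           bands = data.frame(name = "delta", f_lo = 0.1, f_hi = 3),
           pairs = data.frame(subject = pairs$subject, chA = "a", chB = "b",
                              roiA = pairs$roiA, roiB = pairs$roiB),
           normalized = TRUE, nTrials = 60L, baselineWindow = c(-1, -0.25))
  top <- topPairs(p, period = c(0, 1.05), threshold = 300)
  expect_equal(nrow(top), 2)            # MOG-SPL below 300% excluded
  expect_equal(top$roiA, c("IPS", "IPS"))
  expect_equal(top$roiB, c("MOG", "SPL"))  # ordered by latency 0.2 < 0.5
  expect_lt(max(abs(top$latency - c(0.2, 0.5))), 0.06)
  topN <- topPairs(p, period = c(0, 1.05), n = 1, threshold = 300)
  expect_equal(nrow(topN), 1)
})
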