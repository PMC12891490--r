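# Multitaper decomposition and baseline z-score normalization.

# Small epoched fixture around a given signal generator g(t, ch, tr).
signalTensor <- function(g, window = c(-1.5, 1.5), nCh = 1L, nTr = 3L,
                         fs = 512) {
  n <- round(diff(window) * fs) + 1L
  tvec <- window[1] + (0:(n - 1)) / fs
  dat <- array(0, c(n, nCh, nTr))
  for (ch in seq_len(nCh)) for (tr in seq_len(nTr))
    dat[, ch, tr] <- g(tvec, ch, tr)
  trials <- data.frame(trial = seq_len(nTr))
  attr(trials, "roleOnsets") <- c(N1 = 0)
  new("TrialTensor", data = dat, time = tvec, fs = fs,
      channels = data.frame(name = paste0("ch", seq_len(nCh)),
                            subject = "s01", shank = NA_character_,
                            contact = NA_integer_, roi = NA_character_,
                            flags = NA_character_),
      trials = trials, mask = array(FALSE, dim(dat)))
}

test_that("spectrogram grid: 31.25 ms hop and 2 Hz bins up to 120 Hz", {
  tt <- signalTensor(function(t, ch, tr) rnorm(length(t)))
  sp <- multitaperSpectrogram(tt)
  expect_equal(unique(round(diff(timeAxis(sp)), 10)), 16 / 512)
  expect_equal(16 / 512, 0.03125)                     # exactly 31.25 ms
  expect_equal(frequencyAxis(sp), seq(0, 120, by = 2))
  expect_error(multitaperSpectrogram(cropTrials(tt, c(0, 0.2))), "longer")
})

test_that("a pure 20 Hz sinusoid peaks in the 20 Hz bin in every window", {
  tt <- signalTensor(function(t, ch, tr) sin(2 * pi * 20 * t))
  sp <- multitaperSpectrogram(tt)
  peaks <- apply(sp@values[, , 1, 1], 1, which.max)
  expect_true(all(frequencyAxis(sp)[peaks] == 20))
})

test_that("white noise gives a flat mean spectrum", {
  set.seed(8)
  # non-overlapping windows so the 400 estimates per bin are independent
  tt <- signalTensor(function(t, ch, tr) rnorm(length(t)),
                     window = c(-2, 2), nTr = 50L)
  sp <- multitaperSpectrogram(tt, hopSamples = 256L)
  stopifnot(dim(sp@values)[1] * dim(sp@values)[4] >= 200)
  m <- apply(sp@values[, , 1, ], 1:2, mean)   # window x freq
  bandMean <- colMeans(m)
  inner <- 3:59                                # avoid DC and band edges
  expect_lt(diff(range(bandMean[inner])), 1)   # within 1 dB
})

test_that("baseline normalization contract: mean 0%, SD 100% per bin", {
  set.seed(9)
  tt <- signalTensor(function(t, ch, tr) rnorm(length(t), sd = 1 + ch),
                     nCh = 2L, nTr = 5L)
  sp <- multitaperSpectrogram(tt)
  ns <- baselineNormalize(sp, c(-1, -0.25))
  bIdx <- which(timeAxis(ns) >= -1 & timeAxis(ns) <= -0.25)
  for (ch in 1:2) {
    base <- matrix(aperm(ns@values[bIdx, , ch, , drop = FALSE],
                         c(1, 4, 2, 3)), ncol = length(frequencyAxis(ns)))
    expect_equal(max(abs(colMeans(base))), 0, tolerance = 1e-6)
    expect_equal(max(abs(apply(base, 2, sd) - 100)), 0, tolerance = 1e-6)
  }
  expect_true(isNormalized(ns))
  expect_error(baselineNormalize(ns), "already normalized")
})

test_that("constant-power input is degenerate for normalization (sigma = 0)", {
  tt <- signalTensor(function(t, ch, tr) rep(1, length(t)))
  sp <- multitaperSpectrogram(tt)
  expect_error(baselineNormalize(sp), "sigma = 0")
})

test_that("band-limited power increase maps to positive normalized values
           in that band only", {
  set.seed(10)
  bp <- ieegnet:::designBandpass(c(60, 90), 512)
  tt <- signalTensor(function(t, ch, tr) {
    x <- rnorm(length(t))
    add <- ieegnet:::zeroPhase(bp, rnorm(length(t))) * 3
    x + add * (t > 0)                        # extra 60-90 Hz power post-baseline
  }, window = c(-1.5, 1.5), nTr = 8L)
  ns <- baselineNormalize(multitaperSpectrogram(tt), c(-1, -0.25))
  post <- which(timeAxis(ns) > 0.3 & timeAxis(ns) < 1)
  avg <- apply(ns@values[post, , 1, ], 2, mean)   # per frequency bin
  fr <- frequencyAxis(ns)
  expect_gt(min(avg[fr >= 64 & fr <= 86]), 100)
  expect_lt(max(abs(avg[fr <= 40])), 100)
})

test_that("masked samples blank exactly the windows they touch", {
  tt <- signalTensor(function(t, ch, tr) rnorm(length(t)), nTr = 2L)
  tt@mask[760:780, 1, 2] <- TRUE
  sp <- multitaperSpectrogram(tt)
  bad <- is.na(sp@values[, 1, 1, 2])
  # oracle: window [start, start+255] intersects the masked run
  starts <- seq(1, dim(tt@data)[1] - 255, by = 16)
  expect_equal(bad, starts + 255 >= 760 & starts <= 780)
  expect_false(anyNA(sp@values[, , 1, 1]))
})

test_that("ROI spectrogram equals the nested channel/trial mean", {
  set.seed(11)
  vals <- array(rnorm(10 * 4 * 5 * 6), c(10, 4, 5, 6))
  sp <- makeSpec(vals, times = seq(0, 0.9, 0.1), freqs = seq(0, 6, 2))
  sp@channels$roi <- c("A", "A", "A", "B", "B")
  out <- roiSpectrogram(sp, roi = "A")
  oracle <- matrix(0, 10, 4)
  for (ti in 1:10) for (fi in 1:4)
    oracle[ti, fi] <- mean(vapply(1:3, function(ch)
      mean(vals[ti, fi, ch, ]), 0))
  expect_equal(unclass(out)[1:10, 1:4], oracle, ignore_attr = TRUE)
  expect_equal(attr(out, "nChannels"), 3)
  # single-channel ROI equals that channel's trial average
  sp@channels$roi <- c("A", "B", "B", "B", "B")
  one <- roiSpectrogram(sp, roi = "A")
  expect_equal(unclass(one)[1:10, 1:4],
               apply(vals[, , 1, ], c(1, 2), mean), ignore_attr = TRUE)
  # two channels +a and -a average to zero
  v2 <- vals; v2[, , 2, ] <- -v2[, , 1, ]
  sp2 <- makeSpec(v2, times = seq(0, 0.9, 0.1), freqs = seq(0, 6, 2))
  sp2@channels$roi <- c("C", "C", "D", "D", "D")
  expect_equal(max(abs(roiSpectrogram(sp2, roi = "C"))), 0)
  expect_error(roiSpectrogram(sp, roi = "ZZ"), "no channels")
})

test_that("a DC offset leaves the spectrogram unchanged once the high-pass
           has run", {
  set.seed(12)
  fs <- 512
  base <- rnorm(30 * fs)
  mk <- function(x) filterChain(Recording(matrix(x, ncol = 1), fs,
                                          data.frame(name = "c1")))
  f1 <- signalMatrix(mk(base))[, 1]
  f2 <- signalMatrix(mk(base + 250))[, 1]
  t1 <- signalTensor(function(t, ch, tr) f1[1:length(t)])
  t2 <- signalTensor(function(t, ch, tr) f2[1:length(t)])
  s1 <- multitaperSpectrogram(t1)@values[, -1, 1, 1]
  s2 <- multitaperSpectrogram(t2)@values[, -1, 1, 1]
  expect_equal(s1, s2, tolerance = 1e-6)
})
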