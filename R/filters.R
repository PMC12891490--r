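# Internal zero-phase filtering machinery.
#
# All task-related filtering is zero-phase: the filter is applied forward and
# backward, squaring the magnitude response and cancelling the phase. Edge
# transients are controlled by odd-reflection padding whose length is derived
# from the slowest pole of the design. Very-low-cutoff high-pass designs are
# numerically unstable as a single transfer function in double precision, so
# the high-pass is realized as cascaded analytically designed second-order
# sections.

# Pad length from the largest pole radius: ~7 time constants, capped.
padLenFromPoles <- function(a, nmax) {
  r <- suppressWarnings(max(Mod(polyroot(rev(a)))))
  if (!is.finite(r) || r >= 1) r <- 1 - 1e-6
  min(nmax, max(64L, ceiling(-7 / log(r))))
}

# Odd-reflection padding around both endpoints.
oddReflectPad <- function(x, pad) {
  n <- length(x)
  pad <- min(pad, n - 1L)
  c(2 * x[1] - x[(pad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - pad)])
}

# Zero-phase run of a single (b, a) section with reflection padding.
zeroPhaseTF <- function(b, a, x, pad = NULL) {
  n <- length(x)
  if (is.null(pad)) pad <- padLenFromPoles(a, n - 1L)
  xp <- oddReflectPad(x, pad)
  y <- signal::filter(b, a, xp)
  y <- rev(signal::filter(b, a, rev(y)))
  y[(pad + 1L):(pad + n)]
}

# Apply a zero-phase filter (Arma or SOS list) to a vector or the columns of
# a matrix.
zeroPhase <- function(filt, x) {
  runner <- function(v) {
    if (inherits(filt, "Arma") || (is.list(filt) && !is.null(filt$b))) {
      zeroPhaseTF(filt$b, filt$a, v)
    } else {
      for (sec in filt) v <- zeroPhaseTF(sec$b, sec$a, v)
      v
    }
  }
  if (is.matrix(x)) {
    for (j in seq_len(ncol(x))) x[, j] <- runner(x[, j])
    x
  } else runner(x)
}

# Butterworth high-pass of order n as cascaded biquads, designed from the
# analog prototype (poles exp(i*pi*(2k+n-1)/(2n))), high-pass transformed and
# bilinear-mapped with prewarping. Each section is gain-normalized at Nyquist.
butterHighpassSOS <- function(n, fc, fs) {
  wc <- 2 * fs * tan(pi * fc / fs)
  k <- seq_len(n)
  proto <- exp(1i * pi * (2 * k + n - 1) / (2 * n))
  php <- wc / proto                       # analog high-pass poles
  zp <- (2 * fs + php) / (2 * fs - php)   # bilinear map; zeros all at z = 1
  sos <- list()
  used <- rep(FALSE, n)
  nyqGain <- function(b, a) {
    s <- (-1)^(seq_along(b) - 1)
    abs(sum(b * s) / sum(a * s[seq_along(a)]))
  }
  for (i in which(Im(php) > 1e-12 * abs(php))) {
    j <- which(!used & abs(php - Conj(php[i])) < 1e-9 * abs(php[i]))
    j <- setdiff(j, i)[1]
    used[c(i, j)] <- TRUE
    a <- c(1, -2 * Re(zp[i]), Mod(zp[i])^2)
    b <- c(1, -2, 1)
    b <- b / nyqGain(b, a)
    sos[[length(sos) + 1L]] <- list(b = b, a = a)
  }
  for (i in which(!used & abs(Im(php)) <= 1e-12 * abs(php))) {
    a <- c(1, -Re(zp[i]))
    b <- c(1, -1)
    b <- b / nyqGain(b, a)
    sos[[length(sos) + 1L]] <- list(b = b, a = a)
  }
  sos
}

# Standard designs used across the pipeline. "6th-order" band-pass/stop
# filters are butter(3, ...) (band transforms double the prototype order).
designBandpass <- function(band, fs, order = 3L) {
  signal::butter(order, band / (fs / 2), type = "pass")
}

designBandstop <- function(band, fs, order = 3L) {
  signal::butter(order, band / (fs / 2), type = "stop")
}

designLowpass <- function(fc, fs, order = 6L) {
  signal::butter(order, fc / (fs / 2), type = "low")
}

# Anti-alias decimation filter: Chebyshev type I, 0.05 dB passband ripple.
designAntialias <- function(fc, fs, order = 8L, ripple = 0.05) {
  signal::cheby1(order, ripple, fc / (fs / 2), type = "low")
}

# Analytic signal via the frequency-domain Hilbert transform, column-wise.
analyticSignal <- function(x) {
  single <- !is.matrix(x)
  if (single) x <- matrix(x, ncol = 1L)
  n <- nrow(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  X <- stats::mvfft(x)
  z <- stats::mvfft(X * h, inverse = TRUE) / n
  if (single) z[, 1] else z
}
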