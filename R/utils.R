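# Shared numeric helpers: window functions, running statistics, band-limited
# noise synthesis and the short-time Fourier transform used by both the
# energy and feature modules.

# Periodic Hann window. mean(w) = 0.5 and mean(w^2)/mean(w)^2 = 1.5 exactly,
# so dividing the band-summed power by the bandwidth factor B = 1.5 undoes
# the window's noise bandwidth (see splParams()).
hannWindow <- function(n) {
  stopifnot(n >= 2L)
  0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / n))
}

# Tukey (tapered cosine) window; alpha is the total fraction of the window
# spent in the raised-cosine ramps.
tukeyWindow <- function(n, alpha = 0.5) {
  if (n <= 1L) return(rep(1, n))
  t <- (seq_len(n) - 1) / (n - 1)
  w <- rep(1, n)
  edge <- alpha / 2
  lo <- t < edge
  hi <- t > 1 - edge
  w[lo] <- 0.5 * (1 + cos(pi * (2 * t[lo] / alpha - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * t[hi] / alpha - 2 / alpha + 1)))
  w
}

# Centered moving average with shrinking windows at the edges; O(n) via
# cumulative sums.  The interior (full-window) part is computed without
# per-element bounds checks -- this sits on the cleaning hot path.
runningMean <- function(x, w) {
  n <- length(x)
  w <- max(1L, as.integer(round(w)))
  half <- w %/% 2L
  cs <- cumsum(c(0, x))
  res <- numeric(n)
  if (n > 2L * half) {
    i <- (half + 1L):(n - half)
    res[i] <- (cs[i + half + 1L] - cs[i - half]) / (2L * half + 1L)
    edges <- c(seq_len(half), (n - half + 1L):n)
  } else {
    edges <- seq_len(n)
  }
  for (i in edges) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    res[i] <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  res
}

# DFT bin frequencies in Hz, negative frequencies folded to negative values.
fftFreqs <- function(n, sampleRate) {
  k <- 0:(n - 1)
  k[k > n / 2] <- k[k > n / 2] - n
  k * sampleRate / n
}

# Gaussian noise confined to [low, high] Hz by hard spectral masking,
# rescaled to unit RMS.  The DFT runs at the next 2-3-5-smooth length and
# the result is truncated: a mixed-radix FFT degrades to O(n^2) when n has
# a large prime factor, and event lengths here are arbitrary.
bandNoise <- function(n, sampleRate, low, high) {
  m <- stats::nextn(n, c(2L, 3L, 5L))
  z <- stats::rnorm(m)
  f <- fftFreqs(m, sampleRate)
  keep <- abs(f) >= low & abs(f) <= high
  if (!any(keep)) {
    stop("band [", low, ", ", high, "] Hz contains no DFT bins at sample rate ",
         sampleRate, " Hz")
  }
  Y <- stats::fft(z)
  Y[!keep] <- 0
  x <- Re(stats::fft(Y, inverse = TRUE))[seq_len(n)] / m
  r <- sqrt(mean(x^2))
  if (r == 0) stop("degenerate band-limited noise (zero RMS)")
  x / r
}

# Hann-tapered short-time Fourier transform.  Magnitudes are normalized by
# fftLength * mean(window) (the window's coherent gain) so a unit-amplitude
# sine peaks at ~0.5 in its bin.
stft <- function(x, sampleRate, fftLength, hop) {
  n <- length(x)
  fftLength <- as.integer(fftLength)
  hop <- as.integer(hop)
  if (n < fftLength) stop("signal shorter than one FFT frame")
  starts <- seq.int(1L, n - fftLength + 1L, by = hop)
  idx <- outer(seq_len(fftLength) - 1L, starts, "+")
  frames <- matrix(x[idx], nrow = fftLength)
  w <- hannWindow(fftLength)
  Y <- stats::mvfft(frames * w)
  nb <- fftLength %/% 2L + 1L
  list(time = (starts - 1 + fftLength / 2) / sampleRate,
       freq = (seq_len(nb) - 1) * sampleRate / fftLength,
       mag = Mod(Y[seq_len(nb), , drop = FALSE]) / (fftLength * mean(w)))
}

# Bilinear resampling of a matrix to nRowsOut x nColsOut (separable linear
# interpolation along each axis).
resampleBilinear <- function(m, nRowsOut, nColsOut) {
  interpCols <- function(mat, nOut) {
    nc <- ncol(mat)
    if (nc == 1L) return(mat[, rep(1L, nOut), drop = FALSE])
    pos <- seq(1, nc, length.out = nOut)
    lo <- pmin(floor(pos), nc - 1)
    frac <- pos - lo
    mat[, lo, drop = FALSE] * rep(1 - frac, each = nrow(mat)) +
      mat[, lo + 1, drop = FALSE] * rep(frac, each = nrow(mat))
  }
  t(interpCols(t(interpCols(m, nColsOut)), nRowsOut))
}
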