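# Calibration correction, framed SPL against time-domain oracles, and
# median gating.

test_that("correction factor follows S = Mh + G + 20 log10(1/Vadc)", {
  expect_equal(correctionFactor(calibrationSpec(-185, 20, 1)), -165)
  expect_equal(correctionFactor(calibrationSpec(-185.5, 20, 1)), -165.5)
  expect_equal(correctionFactor(calibrationSpec(-185, 20, 10)), -185)
  expect_error(calibrationSpec(-185, 20, 0), "positive")
})

test_that("full-band sine SPL matches the mean-square oracle over 60 dB", {
  sr <- 16000
  t <- (0:(sr - 1)) / sr
  p <- params16()
  for (A in 10^seq(-3, 0, by = 1)) {
    y <- A * sin(2 * pi * 1234.5 * t)
    expect_lt(abs(frameSpl(y, sr, cal0, p) - 10 * log10(A^2 / 2)), 0.1)
  }
})

test_that("white-noise SPL matches the time-domain mean square", {
  set.seed(21)
  sr <- 16000
  y <- rnorm(2 * sr, 0, 0.05)
  got <- frameSpl(y, sr, cal0, params16())
  expect_lt(abs(got - 10 * log10(mean(y^2))), 0.1)
})

test_that("scaling a frame by 10 adds exactly 20 dB", {
  set.seed(22)
  y <- rnorm(8000, 0, 0.01)
  a <- frameSpl(y, 16000, cal0, params16())
  b <- frameSpl(10 * y, 16000, cal0, params16())
  expect_equal(b - a, 20, tolerance = 1e-9)
})

test_that("out-of-band tones are suppressed by >= 40 dB", {
  sr <- 16000
  y <- 0.1 * sin(2 * pi * 3000 * (0:(sr - 1)) / sr)
  inBand <- frameSpl(y, sr, cal0, splParams(bandLow = 2000, bandHigh = 4000))
  outBand <- frameSpl(y, sr, cal0, splParams(bandLow = 5000, bandHigh = 7000))
  expect_gt(inBand - outBand, 40)
})

test_that("full-band power obeys Parseval with B = 1, S = 0", {
  set.seed(23)
  sr <- 8000
  y <- rnorm(4096, 0, 0.1)
  p1 <- splParams(bandLow = 0, bandHigh = sr / 2, bandwidthFactor = 1)
  got <- 10^(frameSpl(y, sr, cal0, p1) / 10)
  w <- 0.5 * (1 - cos(2 * pi * (seq_along(y) - 1) / length(y)))
  expect_equal(got, mean((y * w / mean(w))^2), tolerance = 1e-6)
})

test_that("framing drops the partial tail and the median is file-wide", {
  set.seed(24)
  sr <- 4000
  rec <- audioRecording(rnorm(120 * sr + 123, 0, 0.02), sr)
  ser <- splSeries(rec, cal0, splParams(frameLength = 0.5, bandHigh = sr / 2))
  expect_identical(length(ser), 240L)
  expect_identical(splMedian(ser), median(spl(ser)))
  expect_lt(max(spl(ser)) - min(spl(ser)), 3)   # stationary noise

  tone <- toneRecording(440, amp = 0.3, dur = 10, sr = sr)
  st <- splSeries(tone, cal0, splParams(frameLength = 0.5, bandHigh = sr / 2))
  expect_lt(max(abs(spl(st) - splMedian(st))), 0.01)
})

test_that("all-zero frames get a -Inf sentinel with a warning", {
  rec <- audioRecording(c(numeric(4000), rnorm(4000, 0, 0.1)), 8000)
  expect_warning(ser <- splSeries(rec, cal0,
                                  splParams(frameLength = 0.5,
                                            bandHigh = 4000)), "-Inf")
  expect_identical(spl(ser)[1], -Inf)
  expect_true(is.finite(spl(ser)[2]))
})

test_that("gating reproduces the hand-traced example", {
  ser <- makeSeries(c(100, 100, 100, 110, 110, 100))
  seg <- candidateSegments(ser, margin = 3, minDuration = 0, mergeGap = 0)
  expect_identical(nrow(seg), 1L)
  expect_equal(seg$start, 1.5)       # frames 4-5 of 0.5 s
  expect_equal(seg$end, 2.5)
  expect_equal(seg$peakTime, 1.75)   # earliest of the tied 110s
  expect_equal(seg$peakExcess, 10)
})

test_that("constant series yield no candidates; margin 0 marks <= half", {
  ser <- makeSeries(rep(97.5, 40))
  expect_identical(nrow(candidateSegments(ser, margin = 0)), 0L)
  set.seed(25)
  noisy <- makeSeries(rnorm(101, 100, 2))
  expect_lte(mean(spl(noisy) > splMedian(noisy)), 0.5)
})

test_that("gating matches the brute-force oracle on random series", {
  set.seed(26)
  for (rep in 1:200) {
    splv <- rnorm(20, 100, 4)
    ser <- makeSeries(splv)
    for (margin in c(0, 3, 6)) {
      got <- candidateSegments(ser, margin, minDuration = 1, mergeGap = 1)
      want <- bruteSegments(splv, 0.5, margin, minDuration = 1, mergeGap = 1)
      expect_equal(got, want, info = sprintf("rep %d margin %g", rep, margin))
    }
  }
})
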