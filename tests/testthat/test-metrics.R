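# Accuracy, SEL metrics and detection time series.

test_that("accuracy is the exact error fraction complement", {
  expect_identical(detectionAccuracy(200, 2), 0.99)
  for (N in c(1, 7, 100, 4188)) expect_identical(detectionAccuracy(N, 0), 1)
  rho <- detectionAccuracy(4188, 33)
  expect_equal(rho, 4155 / 4188)
  expect_identical(round(100 * rho, 2), 99.21)
  expect_identical(detectionAccuracy(10, 10), 0)
  expect_error(detectionAccuracy(0, 0), "positive")
  expect_error(detectionAccuracy(10, 11), "nTotal")
})

test_that("evaluation counts symmetric per-file errors", {
  files <- data.frame(source = sprintf("f%02d.wav", 1:50),
                      vesselPresent = rep(c(TRUE, FALSE), 25))
  labels <- data.frame(file = files$source, label = files$vesselPresent)
  ev <- evaluateDetections(files, labels)
  expect_identical(ev@rho, 1)
  expect_identical(ev@falsePositives + ev@falseNegatives, 0L)

  inverted <- transform(files, vesselPresent = !vesselPresent)
  expect_identical(evaluateDetections(inverted, labels)@rho, 0)

  one <- files
  one$vesselPresent[7] <- !one$vesselPresent[7]
  ev1 <- evaluateDetections(one, labels)
  expect_identical(ev1@nError, 1L)
  expect_equal(ev1@rho, 49 / 50)

  # symmetry: flipping labels and predictions together preserves rho
  flipped <- evaluateDetections(
    transform(files, vesselPresent = !vesselPresent),
    transform(labels, label = !label))
  expect_identical(flipped@rho, ev@rho)

  expect_error(evaluateDetections(files, labels[-1, ]), "unlabeled")
})

test_that("SEL metrics reproduce the hand trapezoid and its linearity", {
  # many frames at 100 with two adjacent frames at 102 and 104:
  # median 100, excesses 2 and 4 -> area 0.5*(2+4)/2 = 1.5 dB s
  splv <- c(rep(100, 20), 102, 104, rep(100, 20))
  ser <- makeSeries(splv)
  seg <- list(start = 20 * 0.5, end = 22 * 0.5)
  m <- selMetrics(ser, seg)
  expect_equal(m@peakDifference, 4)
  expect_equal(m@meanDifference, 3)
  expect_equal(m@areaSize, 1.5)

  # doubling the excesses doubles every metric
  ser2 <- makeSeries(c(rep(100, 20), 104, 108, rep(100, 20)))
  m2 <- selMetrics(ser2, seg)
  expect_equal(m2@peakDifference, 8)
  expect_equal(m2@meanDifference, 6)
  expect_equal(m2@areaSize, 3)

  # constant-at-median segment
  flat <- makeSeries(rep(95, 30))
  m0 <- selMetrics(flat, list(start = 2, end = 8))
  expect_identical(c(m0@peakDifference, m0@meanDifference, m0@areaSize),
                   c(0, 0, 0))
})

test_that("trapezoid area agrees with a halved-spacing Riemann oracle", {
  fl <- 0.5
  centers <- (1:120 - 0.5) * fl
  bump <- 8 * exp(-((centers - 30)^2) / 18)
  splv <- 100 + ifelse(bump > 0.5, bump, 0)
  ser <- makeSeries(splv, fl)
  seg <- list(start = 20, end = 40)
  m <- selMetrics(ser, seg)

  inSeg <- centers >= seg$start & centers <= seg$end
  exc <- pmax(splv - median(splv), 0)
  tFine <- seq(min(centers[inSeg]), max(centers[inSeg]), by = fl / 2)
  excFine <- approx(centers, exc, tFine)$y
  riemann <- sum(excFine[-length(excFine)]) * fl / 2
  expect_lt(abs(m@areaSize - riemann) / riemann, 0.02)

  # the linear-energy variant exists and exceeds zero here
  expect_true(is.finite(selAreaLinear(ser, seg)))
})

test_that("cumulative SEL sums per station", {
  areas <- data.frame(station = c("9M", "9M", "9M"),
                      areaSize = c(1.0, 2.5, 0.5))
  expect_equal(cumulativeSel(areas)$selCum, 4.0)
  expect_identical(nrow(cumulativeSel(areas[0, ])), 0L)

  two <- data.frame(station = c("9M", "37M", "9M", "37M"),
                    areaSize = c(1, 10, 2, 20))
  got <- cumulativeSel(two)
  expect_equal(got$selCum[got$station == "9M"], 3)
  expect_equal(got$selCum[got$station == "37M"], 30)
  shuffledGot <- cumulativeSel(two[c(3, 1, 4, 2), ])
  expect_equal(got, shuffledGot)
})

test_that("detection time series grids counts by date and hour", {
  ts <- as.POSIXct(c("2018-07-01 09:05:00", "2018-07-01 09:45:00",
                     "2018-07-01 14:10:00", "2018-07-01 03:00:00",
                     "2018-07-02 09:00:00"), tz = "UTC")
  files <- data.frame(source = sprintf("f%d.wav", 1:5),
                      vesselPresent = c(TRUE, TRUE, TRUE, FALSE, FALSE),
                      timestamp = ts)
  g <- detectionTimeseries(files)
  cell <- function(d, h) g[g$date == as.Date(d) & g$hour == h, ]
  expect_identical(cell("2018-07-01", 9)$nDetections, 2L)
  expect_identical(cell("2018-07-01", 14)$nDetections, 1L)
  # covered cell with zero detections vs uncovered cell
  expect_identical(cell("2018-07-01", 3)$nDetections, 0L)
  expect_identical(cell("2018-07-01", 3)$nFiles, 1L)
  expect_identical(cell("2018-07-01", 12)$nFiles, 0L)
  expect_identical(sum(g$nDetections), 3L)      # conservation
  expect_identical(sum(g$nFiles), 5L)

  files$timestamp[2] <- NA
  expect_warning(g2 <- detectionTimeseries(files), "without timestamps")
  expect_identical(sum(g2$nDetections), 2L)
})

test_that("timestamps parse from DSG-style filenames", {
  got <- timestampFromFilename(c("37M_1216_20180701_090500.wav", "odd.wav"))
  expect_identical(format(got[1], "%Y-%m-%d %H:%M"), "2018-07-01 09:05")
  expect_true(is.na(got[2]))
})
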