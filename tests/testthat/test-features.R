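# Spectrogram feature windows and training-set assembly.

test_that("spectrogram localizes a pure tone and has the contracted width", {
  sr <- 16000
  rec <- toneRecording(1000, amp = 0.2, dur = 2, sr = sr)
  sg <- spectrogramMatrix(rec, fftLength = 512, hop = 256)
  expect_identical(ncol(sg$mag),
                   as.integer(floor((2 * sr - 512) / 256) + 1))
  targetBin <- which.min(abs(sg$freq - 1000))
  expect_true(all(apply(sg$mag, 2, which.max) == targetBin))
})

test_that("a broadband burst dominates background columns", {
  spec <- sceneSpec(duration = 20, sampleRate = 16000, snapRate = 0,
                    events = vesselEvent("burst_narrow", 10, duration = 5,
                                         level = 12), seed = 31)
  scn <- simulateScene(spec)
  sg <- spectrogramMatrix(scn$recording, 512, 256)
  colE <- colSums(sg$mag^2)
  burstCols <- sg$time > 11 & sg$time < 14
  bgCols <- sg$time < 8
  expect_gt(mean(colE[burstCols]) / mean(colE[bgCols]), 10)
})

test_that("feature extraction is translation-invariant and shape-stable", {
  set.seed(32)
  sr <- 16000
  fp <- features16()
  block <- rnorm(round(fp@deltaT * sr), 0, 0.05)
  rec <- audioRecording(rep(block, 3), sr)
  c1 <- fp@deltaT / 2
  f1 <- extractFeature(rec, c1, fp)
  f2 <- extractFeature(rec, c1 + fp@deltaT, fp)
  expect_equal(featureValues(f1), featureValues(f2))
  expect_identical(dim(featureValues(f1)), c(32L, 32L))

  # near the file start the window is zero-padded but keeps its shape
  f3 <- extractFeature(rec, 0.5, fp)
  expect_identical(dim(featureValues(f3)), c(32L, 32L))
  expect_error(extractFeature(rec, duration(rec) + 1, fp), "outside")
})

test_that("standardization removes loudness and hits its moments", {
  set.seed(33)
  sr <- 16000
  fp <- features16()
  x <- rnorm(8 * sr, 0, 0.02)
  r1 <- audioRecording(x, sr)
  r10 <- audioRecording(10 * x, sr)
  f1 <- featureValues(extractFeature(r1, 4, fp))
  f10 <- featureValues(extractFeature(r10, 4, fp))
  expect_equal(f1, f10, tolerance = 1e-8)   # dB shift removed
  expect_lt(abs(mean(f1)), 1e-9)
  expect_lt(abs(stats::var(as.vector(f1)) - 1), 1e-6)
})

test_that("training sets honour counts, determinism and burst exclusion", {
  spec <- sceneSpec(duration = 120, sampleRate = 16000, snapRate = 2,
    events = rbind(vesselEvent("burst_narrow", 20, 6, 12),
                   vesselEvent("burst_narrow", 60, 6, 12),
                   vesselEvent("burst_wide", 90, 15, 12)), seed = 34)
  scn <- simulateScene(spec, sourceId = "s1")
  ev <- cbind(source = "s1", scn$truth$events)
  fp <- features16()

  ts <- buildTrainingSet(list(scn$recording), ev, fp,
                         negativesPerPositive = 15, seed = 9)
  expect_identical(sum(ts@targets == 1L), 3L)
  expect_identical(sum(ts@targets == 0L), 45L)

  ts2 <- buildTrainingSet(list(scn$recording), ev, fp,
                          negativesPerPositive = 15, seed = 9)
  expect_identical(
    vapply(ts@features, function(f) f@centerTime, numeric(1)),
    vapply(ts2@features, function(f) f@centerTime, numeric(1)))
  ts3 <- buildTrainingSet(list(scn$recording), ev, fp,
                          negativesPerPositive = 15, seed = 10)
  expect_false(identical(
    vapply(ts@features, function(f) f@centerTime, numeric(1)),
    vapply(ts3@features, function(f) f@centerTime, numeric(1))))

  # negatives keep a full window away from every burst
  negC <- vapply(ts@features[ts@targets == 0L], function(f) f@centerTime,
                 numeric(1))
  for (i in seq_len(nrow(ev)))
    expect_true(all(negC <= ev$start[i] - fp@deltaT |
                    negC >= ev$end[i] + fp@deltaT))
})

test_that("in-band energy alone nearly separates the classes (sanity floor)", {
  spec <- sceneSpec(duration = 120, sampleRate = 16000, snapRate = 2,
    events = rbind(vesselEvent("burst_narrow", 20, 6, 12),
                   vesselEvent("burst_narrow", 60, 6, 12),
                   vesselEvent("burst_wide", 90, 15, 12)), seed = 35)
  scn <- simulateScene(spec, sourceId = "s1")
  ev <- cbind(source = "s1", scn$truth$events)
  ts <- buildTrainingSet(list(scn$recording), ev, features16(),
                         negativesPerPositive = 15, seed = 11)
  # trivial classifier: band SPL of a 1 s frame at each window center
  p <- splParams(bandLow = 800, bandHigh = 7000)
  sr <- sampleRate(scn$recording)
  e <- vapply(ts@features, function(f) {
    i0 <- max(1, round((f@centerTime - 0.5) * sr))
    frameSpl(samples(scn$recording)[i0:(i0 + sr - 1)], sr, cal0, p)
  }, numeric(1))
  thr <- mean(range(e))
  acc <- mean((e > thr) == (ts@targets == 1L))
  expect_gte(acc, 0.9)
})
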