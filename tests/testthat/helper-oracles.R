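# Shared fixtures and independent oracles used across the suite.

# Calibration with zero correction: SPL values come out in plain dB relative
# to ADC-normalized power, which keeps oracles self-contained.
cal0 <- calibrationSpec(sensitivity = 0, gain = 0, vAdc = 1)

# Parameter sets for the reduced 16 kHz study rate used throughout testing.
params16 <- function() splParams(bandHigh = 8000)
features16 <- function() featureParams(fLow = 800, fHigh = 7000,
                                       fftLength = 512, hop = 256)
config16 <- function(...) scanConfig(energy = params16(),
                                     features = features16(), ...)

toneRecording <- function(freq, amp = 0.1, dur = 1, sr = 16000) {
  t <- (seq_len(round(dur * sr)) - 1) / sr
  audioRecording(amp * sin(2 * pi * freq * t), sr, sourceId = "tone")
}

# Independent brute-force implementation of the median-gating rule, written
# as a naive frame-by-frame scan (no vectorized grouping) so it shares no
# code with candidateSegments().
bruteSegments <- function(splv, frameLength, margin, minDuration, mergeGap) {
  med <- median(splv)
  nf <- length(splv)
  marked <- splv > med + margin
  gapFrames <- floor(mergeGap / frameLength + 1e-9)
  segs <- list()
  i <- 1
  while (i <= nf) {
    if (!marked[i]) { i <- i + 1; next }
    first <- i
    last <- i
    j <- i + 1
    gap <- 0
    while (j <= nf) {
      if (marked[j]) { last <- j; gap <- 0 }
      else { gap <- gap + 1; if (gap > gapFrames) break }
      j <- j + 1
    }
    start <- (first - 1) * frameLength
    end <- last * frameLength
    if (end - start >= minDuration) {
      pk <- first
      for (q in first:last) if (splv[q] > splv[pk]) pk <- q
      segs[[length(segs) + 1]] <- data.frame(
        start = start, end = end, peakTime = (pk - 0.5) * frameLength,
        peakExcess = splv[pk] - med)
    }
    i <- last + gap + 1
  }
  if (length(segs) == 0)
    return(data.frame(start = numeric(), end = numeric(),
                      peakTime = numeric(), peakExcess = numeric()))
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  out
}

makeSeries <- function(splv, frameLength = 0.5, sourceId = "test") {
  new("FrameEnergySeries",
      frameCenters = (seq_along(splv) - 0.5) * frameLength,
      spl = splv, splMedian = median(splv), frameLength = frameLength,
      sourceId = sourceId)
}

# Hand-rolled forward pass (vector in, scalar out) independent of the
# package's matrix implementation.
oracleForward <- function(weights, biases, x) {
  a <- as.numeric(x)
  nl <- length(weights)
  for (l in seq_len(nl - 1)) a <- tanh(weights[[l]] %*% a + biases[[l]])
  z <- weights[[nl]] %*% a + biases[[nl]]
  1 / (1 + exp(-z))
}

# Seeded, linearly separable two-class set of 8x8 feature windows.
blobTrainingSet <- function(nPerClass = 250, seed = 1) {
  set.seed(seed)
  mk <- function(mu, label) lapply(seq_len(nPerClass), function(i)
    new("FeatureWindow", values = matrix(rnorm(64, mu, 0.4), 8, 8),
        centerTime = 0, sourceId = "blob", label = label))
  trainingSet(c(mk(-1, 0L), mk(1, 1L)),
              c(rep(0L, nPerClass), rep(1L, nPerClass)))
}

# In-memory training scenes plus a trained model for scanner tests, built
# once and cached.
.testCache <- new.env(parent = emptyenv())

scannerModel <- function() {
  if (!is.null(.testCache$model)) return(.testCache$model)
  recs <- list()
  events <- NULL
  for (i in 1:10) {
    ev <- if (i <= 6)
      vesselEvent(if (i %% 2) "burst_narrow" else "burst_wide",
                  start = 10 + 3 * i, duration = if (i %% 2) 6 else 14,
                  level = 12)
    else emptyEvents()
    spec <- sceneSpec(duration = 60, sampleRate = 16000, snapRate = 5,
                      chorusEnabled = i %in% c(7, 8), events = ev,
                      seed = 100 + i)
    scn <- simulateScene(spec, sourceId = sprintf("train_%02d", i))
    recs[[i]] <- removeSnaps(scn$recording)
    if (nrow(scn$truth$events))
      events <- rbind(events, cbind(source = sourceId(recs[[i]]),
                                    scn$truth$events))
  }
  ts <- buildTrainingSet(recs, events, features16(),
                         negativesPerPositive = 12, seed = 7)
  model <- trainNetwork(initNetwork(32 * 32, seed = 7), ts, seed = 7)
  .testCache$model <- model
  model
}
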