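# Stage 2 inputs: fixed-size spectrogram feature windows and training-set
# assembly.
#
# A feature window is the log-magnitude spectrogram of a deltaT-second
# stretch of audio centered on a candidate instant, restricted to the
# 800-10000 Hz band, bilinearly resampled to a fixed grid and standardized
# to zero mean / unit variance within the window.  Standardization makes the
# classifier judge spectro-temporal shape, not loudness -- loudness is stage
# 1's job -- and makes the score invariant to the absolute gain of the
# source audio.

#' Spectrogram of a recording
#'
#' Hann-tapered short-time DFT magnitudes with physical axes.
#'
#' @param rec an \code{\link{audioRecording}} (>= \code{fftLength} samples).
#' @param fftLength DFT length in samples.
#' @param hop hop between columns in samples.
#' @return list with \code{time} (s), \code{freq} (Hz, up to Nyquist) and
#'   \code{mag} (frequency x time magnitude matrix).  The number of columns
#'   is \code{floor((N - fftLength)/hop) + 1}.
#' @export
spectrogramMatrix <- function(rec, fftLength = 2048, hop = fftLength %/% 2) {
  stopifnot(is(rec, "AudioRecording"))
  if (length(rec@samples) < fftLength)
    stop("recording shorter than one FFT frame")
  stft(rec@samples, rec@sampleRate, fftLength, hop)
}

#' Extract one feature window
#'
#' Cuts \code{[centerTime - deltaT/2, centerTime + deltaT/2]} (zero-padded
#' where it extends past the file so the output shape never changes),
#' computes its spectrogram, restricts it to \code{[fLow, fHigh]} Hz (the
#' upper edge clamped to Nyquist), converts to dB, resamples to the
#' \code{gridTime x gridFreq} grid and standardizes within the window.
#'
#' @param rec an \code{\link{audioRecording}}.
#' @param centerTime window center in seconds (must lie inside the file).
#' @param params a \code{\link{featureParams}}.
#' @param label optional 0/1 class label stored with the window.
#' @return A \code{\link{FeatureWindow-class}}.
#' @export
extractFeature <- function(rec, centerTime, params = featureParams(),
                           label = NA_integer_) {
  stopifnot(is(rec, "AudioRecording"), is(params, "FeatureParams"))
  sr <- rec@sampleRate
  n <- length(rec@samples)
  if (centerTime < 0 || centerTime > n / sr)
    stop("centerTime outside recording")

  ns <- as.integer(round(params@deltaT * sr))
  startIdx <- as.integer(floor((centerTime - params@deltaT / 2) * sr)) + 1L
  idx <- startIdx:(startIdx + ns - 1L)
  snippet <- numeric(ns)
  valid <- idx >= 1L & idx <= n
  snippet[valid] <- rec@samples[idx[valid]]

  sg <- stft(snippet, sr, params@fftLength, params@hop)
  fHi <- min(params@fHigh, sr / 2)
  rows <- which(sg$freq >= params@fLow & sg$freq <= fHi)
  if (length(rows) < 2)
    stop("feature band contains fewer than 2 spectrogram rows")
  db <- 20 * log10(sg$mag[rows, , drop = FALSE] + 1e-12)

  vals <- resampleBilinear(db, params@gridFreq, params@gridTime)
  vals <- t(vals)                      # rows = time, cols = frequency
  s <- stats::sd(vals)
  vals <- if (s > 0) (vals - mean(vals)) / s else vals * 0
  new("FeatureWindow", values = vals, centerTime = centerTime,
      sourceId = rec@sourceId, label = as.integer(label))
}

#' Assemble a training set from recordings with event logs
#'
#' Positives are windows centered on the midpoints of logged burst-broadband
#' events; negatives are sampled (seeded, uniformly over valid time) at
#' least \code{deltaT} seconds away from any burst, \code{negativesPerPositive}
#' per positive.  Recordings are matched to events by \code{sourceId}.
#'
#' @param recordings list of \code{\link{audioRecording}} objects.
#' @param events data.frame with columns \code{source}, \code{kind},
#'   \code{start}, \code{end}; rows with kind \code{burst_narrow} or
#'   \code{burst_wide} are the positives.
#' @param params a \code{\link{featureParams}}.
#' @param negativesPerPositive negatives sampled per positive (default 15,
#'   mirroring the roughly 1:15 class ratio of curated vessel feature sets).
#' @param seed RNG seed for negative placement.
#' @return A \code{\link{TrainingSet-class}}.
#' @export
buildTrainingSet <- function(recordings, events, params = featureParams(),
                             negativesPerPositive = 15, seed = 1) {
  stopifnot(is.list(recordings), is.data.frame(events))
  ids <- vapply(recordings, sourceId, character(1))
  names(recordings) <- ids
  dt <- params@deltaT

  bb <- events[events$kind %in% c("burst_narrow", "burst_wide"), , drop = FALSE]
  if (nrow(bb) == 0) stop("no burst events available for positives")
  if (!all(bb$source %in% ids))
    stop("events refer to unknown recordings: ",
         paste(setdiff(unique(bb$source), ids), collapse = ", "))

  positives <- lapply(seq_len(nrow(bb)), function(i) {
    r <- recordings[[bb$source[i]]]
    ctr <- (bb$start[i] + bb$end[i]) / 2
    # slide edge-straddling windows inside the file (as the scanner does)
    if (duration(r) >= dt) ctr <- min(max(ctr, dt / 2), duration(r) - dt / 2)
    extractFeature(r, ctr, params, label = 1L)
  })

  # valid negative intervals per recording: [dt/2, dur - dt/2] minus
  # [start - dt, end + dt] around every burst
  negIntervals <- lapply(recordings, function(r) {
    dur <- duration(r)
    lo <- dt / 2
    hi <- dur - dt / 2
    if (hi <= lo) return(cbind(numeric(), numeric()))
    iv <- cbind(lo, hi)
    forb <- bb[bb$source == sourceId(r), , drop = FALSE]
    for (j in seq_len(nrow(forb))) {
      a <- forb$start[j] - dt
      b <- forb$end[j] + dt
      newIv <- NULL
      for (k in seq_len(nrow(iv))) {
        s <- iv[k, 1]; e <- iv[k, 2]
        if (b <= s || a >= e) newIv <- rbind(newIv, c(s, e))
        else {
          if (a > s) newIv <- rbind(newIv, c(s, a))
          if (b < e) newIv <- rbind(newIv, c(b, e))
        }
      }
      iv <- if (is.null(newIv)) cbind(numeric(), numeric()) else newIv
    }
    iv
  })
  lens <- vapply(negIntervals, function(iv)
    if (nrow(iv)) sum(iv[, 2] - iv[, 1]) else 0, numeric(1))
  if (sum(lens) <= 0) stop("no valid negative regions available")

  nNeg <- as.integer(round(length(positives) * negativesPerPositive))
  oldSeed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  recPick <- sample.int(length(recordings), nNeg, replace = TRUE,
                        prob = lens / sum(lens))
  u <- stats::runif(nNeg)
  negatives <- lapply(seq_len(nNeg), function(i) {
    iv <- negIntervals[[recPick[i]]]
    w <- iv[, 2] - iv[, 1]
    pos <- u[i] * sum(w)
    cw <- cumsum(w)
    k <- which(pos <= cw + 1e-12)[1]
    t0 <- iv[k, 1] + (pos - c(0, cw)[k])
    extractFeature(recordings[[recPick[i]]], t0, params, label = 0L)
  })
  if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, globalenv())

  trainingSet(c(positives, negatives),
              c(rep(1L, length(positives)), rep(0L, length(negatives))))
}

#' Flatten a training set into a design matrix
#'
#' @param ts a \code{\link{TrainingSet-class}}.
#' @return list with \code{x} (n x inputDim matrix, windows flattened
#'   column-major) and \code{y} (0/1 targets).
#' @export
trainingMatrix <- function(ts) {
  stopifnot(is(ts, "TrainingSet"))
  if (length(ts@features) == 0) stop("empty training set")
  d <- length(ts@features[[1]]@values)
  x <- t(vapply(ts@features, function(f) as.vector(f@values), numeric(d)))
  list(x = x, y = as.numeric(ts@targets))
}
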