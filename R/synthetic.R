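# Synthetic estuarine soundscape scenes: Gaussian broadband background,
# Poisson snapping-shrimp clicks, slowly amplitude-modulated fish chorus
# below 800 Hz, and vessel events (burst-broadband narrow/wide targets plus
# variable-broadband and low-frequency confounders).  Every scene is fully
# determined by its seed, and each scene carries a truth log so the whole
# pipeline is testable without field data.

burstDurationParams <- list(
  burst_narrow = c(mean = 5.9, sd = 2.1),
  burst_wide = c(mean = 15.9, sd = 6.6))

#' Sample burst-broadband durations
#'
#' Durations are drawn from normals with mean 5.9 s / SD 2.1 s (narrow) and
#' mean 15.9 s / SD 6.6 s (wide), truncated below at 0.5 s by resampling.
#'
#' @param n number of draws.
#' @param kind \code{"burst_narrow"} or \code{"burst_wide"}.
#' @param seed optional RNG seed.
#' @return numeric vector of durations in seconds.
#' @export
sampleBurstDurations <- function(n, kind = c("burst_narrow", "burst_wide"),
                                 seed = NULL) {
  kind <- match.arg(kind)
  if (!is.null(seed)) set.seed(seed)
  p <- burstDurationParams[[kind]]
  out <- stats::rnorm(n, p["mean"], p["sd"])
  while (any(out < 0.5))
    out[out < 0.5] <- stats::rnorm(sum(out < 0.5), p["mean"], p["sd"])
  out
}

eventDefaults <- function(kind, duration, level, nyquist) {
  band <- switch(kind,
    burst_narrow = ,
    burst_wide = c(50, min(40000, 0.98 * nyquist)),
    variable_broadband = c(50, min(25000, 0.98 * nyquist)),
    low_frequency = c(50, min(1000, 0.98 * nyquist)))
  if (is.na(duration)) {
    duration <- switch(kind,
      burst_narrow = sampleBurstDurations(1, "burst_narrow"),
      burst_wide = sampleBurstDurations(1, "burst_wide"),
      variable_broadband = stats::runif(1, 40, 90),
      low_frequency = stats::runif(1, 30, 90))
  }
  if (is.na(level)) {
    level <- switch(kind, burst_narrow = 12, burst_wide = 12,
                    variable_broadband = 8, low_frequency = 10)
  }
  list(band = band, duration = duration, level = level)
}

#' Simulate one soundscape scene
#'
#' Builds the waveform described by a \code{\link{sceneSpec}}: Gaussian
#' background at \code{backgroundRms}; snaps as ~1 ms damped sinusoids with
#' random carrier (Poisson arrivals, peak amplitude
#' \code{snapAmplitudeFactor} x background RMS); optional chorus as
#' band-limited noise with a slow sinusoidal amplitude modulation; vessel
#' events as band-limited noise under a Tukey temporal envelope at
#' \code{level} dB above the background RMS.  The waveform is peak-rescaled
#' only if it would clip, with the applied gain recorded in the truth log.
#'
#' @param spec a \code{\link{sceneSpec}}.
#' @param sourceId identifier stored in the returned recording.
#' @return list with \code{recording} (an \code{AudioRecording}) and
#'   \code{truth}: \code{events} (kind, start, end, level),
#'   \code{snapTimes}, \code{bbPresent} and \code{gain}.  Identical seeds
#'   give bit-identical output.
#' @export
simulateScene <- function(spec, sourceId = "scene") {
  stopifnot(is(spec, "SceneSpec"))
  set.seed(spec@seed)
  sr <- spec@sampleRate
  n <- as.integer(round(spec@duration * sr))
  nyq <- sr / 2
  x <- stats::rnorm(n, 0, spec@backgroundRms)

  # fish chorus: band-limited, slowly amplitude-modulated
  if (isTRUE(spec@chorus$enabled)) {
    ch <- bandNoise(n, sr, spec@chorus$band[1], min(spec@chorus$band[2], nyq))
    tt <- (seq_len(n) - 1) / sr
    phase <- stats::runif(1, 0, 2 * pi)
    env <- 1 + spec@chorus$modDepth *
      sin(2 * pi * tt / spec@chorus$modPeriod + phase)
    amp <- spec@backgroundRms * 10^(spec@chorus$level / 20)
    x <- x + amp * ch * env
  }

  # vessel events
  ev <- spec@events
  truthEvents <- NULL
  for (i in seq_len(nrow(ev))) {
    d <- eventDefaults(ev$kind[i], ev$duration[i], ev$level[i], nyq)
    start <- ev$start[i]
    dur <- min(d$duration, spec@duration - start - 1 / sr)
    ne <- max(16L, as.integer(round(dur * sr)))
    i0 <- as.integer(round(start * sr)) + 1L
    i1 <- min(n, i0 + ne - 1L)
    ne <- i1 - i0 + 1L
    w <- bandNoise(ne, sr, d$band[1], d$band[2]) * tukeyWindow(ne, 0.5)
    amp <- spec@backgroundRms * 10^(d$level / 20)
    x[i0:i1] <- x[i0:i1] + amp * w
    truthEvents <- rbind(truthEvents,
      data.frame(kind = ev$kind[i], start = start, end = start + dur,
                 level = d$level, stringsAsFactors = FALSE))
  }
  if (is.null(truthEvents))
    truthEvents <- data.frame(kind = character(), start = numeric(),
                              end = numeric(), level = numeric(),
                              stringsAsFactors = FALSE)

  # snapping shrimp: Poisson arrivals of millisecond damped sinusoids
  snapTimes <- numeric(0)
  nSnaps <- stats::rpois(1, spec@snapRate * spec@duration)
  if (nSnaps > 0) {
    snapTimes <- sort(stats::runif(nSnaps, 0, spec@duration - 0.002))
    ns <- max(8L, as.integer(round(0.001 * sr)))
    tau <- ns / 4
    k <- seq_len(ns) - 1
    peak <- spec@snapAmplitudeFactor * spec@backgroundRms
    fc <- stats::runif(nSnaps, 0.1 * nyq, 0.8 * nyq)
    ph <- stats::runif(nSnaps, 0, 2 * pi)
    for (j in seq_len(nSnaps)) {
      i0 <- as.integer(round(snapTimes[j] * sr)) + 1L
      idx <- i0:min(n, i0 + ns - 1L)
      kk <- k[seq_along(idx)]
      w <- cos(2 * pi * fc[j] * kk / sr + ph[j]) * exp(-kk / tau)
      x[idx] <- x[idx] + peak * w / max(abs(w))   # peak = factor x bg RMS
    }
  }

  gain <- 1
  pk <- max(abs(x))
  if (pk > 1) {
    gain <- 0.99 / pk
    x <- x * gain
  }

  list(recording = audioRecording(x, sr, sourceId = sourceId),
       truth = list(events = truthEvents, snapTimes = snapTimes,
                    bbPresent = any(truthEvents$kind %in%
                                      c("burst_narrow", "burst_wide")),
                    gain = gain))
}

#' Simulate a labeled corpus of WAV files
#'
#' Writes \code{nFiles} scenes derived from \code{template}; exactly
#' \code{round(nFiles * prevalence)} of them contain one or two
#' burst-broadband events, and a seeded fraction of all files carries a
#' fish chorus.  Alongside the WAVs the function writes \code{truth.csv}
#' (per-event records) and \code{labels.csv} in the
#' \code{\link{loadLabels}} format.
#'
#' @param nFiles number of files (> 0).
#' @param prevalence fraction of files with burst events, in \[0, 1\].
#' @param template a \code{\link{sceneSpec}} providing duration, sample
#'   rate, background, snap and chorus settings; its \code{events} slot is
#'   ignored.
#' @param seed master seed; per-file seeds are derived from it.
#' @param outDir output directory (created if needed).
#' @param chorusFraction fraction of files (positives and negatives alike)
#'   given a chorus.
#' @param burstLevel in-band level of injected bursts, dB above background.
#' @return invisible list with \code{paths}, \code{truth} (data.frame
#'   file, kind, start, end, level), \code{labels} (data.frame file,
#'   label), \code{chorusFiles} (names of the files given a chorus) and
#'   \code{dir}.
#' @export
simulateCorpus <- function(nFiles, prevalence, template = sceneSpec(),
                           seed = 1, outDir = tempfile("corpus"),
                           chorusFraction = 0.3, burstLevel = 12) {
  stopifnot(nFiles > 0, prevalence >= 0, prevalence <= 1)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  nPos <- as.integer(round(nFiles * prevalence))
  posIdx <- sort(sample.int(nFiles, nPos))
  chorusIdx <- sort(sample.int(nFiles, round(nFiles * chorusFraction)))
  fileSeeds <- sample.int(2147483646L, nFiles)
  dur <- template@duration

  paths <- character(nFiles)
  truth <- list()
  labels <- list()
  for (i in seq_len(nFiles)) {
    fname <- sprintf("scene_%03d.wav", i)
    events <- emptyEvents()
    if (i %in% posIdx) {
      nEv <- sample(1:2, 1)
      kinds <- sample(c("burst_narrow", "burst_wide"), nEv, replace = TRUE,
                      prob = c(0.7, 0.3))
      # spread starts so events rarely collide; durations sampled in-scene
      lo <- min(5, 0.1 * dur)
      hi <- max(dur - 40, dur * 0.5)
      starts <- sort(stats::runif(nEv, lo, hi))
      gapMin <- min(40, dur / 3)
      if (nEv == 2 && diff(starts) < gapMin)
        starts[2] <- min(starts[1] + gapMin, dur - 1)
      starts <- pmin(starts, dur - min(25, 0.4 * dur))
      for (j in seq_len(nEv))
        events <- rbind(events, vesselEvent(kinds[j], starts[j],
                                            level = burstLevel))
    }
    spec <- initialize(template, events = events, seed = fileSeeds[i],
      chorus = utils::modifyList(template@chorus,
                                 list(enabled = i %in% chorusIdx)))
    scn <- simulateScene(spec, sourceId = fname)
    paths[i] <- file.path(outDir, fname)
    writeWav(scn$recording, paths[i])
    if (nrow(scn$truth$events) > 0)
      truth[[i]] <- cbind(file = fname, scn$truth$events,
                          stringsAsFactors = FALSE)
    labels[[i]] <- data.frame(file = fname,
                              label = as.integer(scn$truth$bbPresent),
                              stringsAsFactors = FALSE)
  }
  truthDf <- if (length(truth)) do.call(rbind, truth[!vapply(truth, is.null,
                                                             logical(1))])
             else data.frame(file = character(), kind = character(),
                             start = numeric(), end = numeric(),
                             level = numeric(), stringsAsFactors = FALSE)
  labelsDf <- do.call(rbind, labels)
  utils::write.csv(truthDf, file.path(outDir, "truth.csv"), row.names = FALSE)
  utils::write.csv(labelsDf, file.path(outDir, "labels.csv"),
                   row.names = FALSE)
  invisible(list(paths = paths, truth = truthDf, labels = labelsDf,
                 chorusFiles = sprintf("scene_%03d.wav", chorusIdx),
                 dir = outDir))
}
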