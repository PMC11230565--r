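# Snapping-shrimp transient removal.
#
# Snaps are millisecond broadband clicks, among the loudest natural sounds in
# estuaries; in spectrograms they appear as vertical stripes across the whole
# band and would leak energy into the vessel feature band.  Detection
# combines an amplitude test against the slow local RMS envelope with a
# millisecond-scale energy confirmation (see cleaningParams()); excised
# samples are refilled by a centered moving average of neighbouring non-snap
# samples.

#' Detect snapping-shrimp transients
#'
#' Flags samples with \code{|x| > spikeFactor * envelope} where the envelope
#' is the running RMS over \code{envelopeWindow} seconds, pads and merges the
#' flagged runs into half-open sample intervals, and keeps only intervals
#' whose fast RMS (over \code{confirmWindow}) exceeds
#' \code{confirmFactor} times the slow envelope somewhere inside -- snaps
#' concentrate energy at the millisecond scale, while isolated Gaussian tail
#' samples do not.
#'
#' @param rec an \code{\link{audioRecording}}.
#' @param params a \code{\link{cleaningParams}}.
#' @return data.frame with integer columns \code{start}, \code{end}: sorted,
#'   non-overlapping half-open intervals \code{[start, end)} in 1-based
#'   sample indices.  Zero rows for clean audio.
#' @export
detectSnaps <- function(rec, params = cleaningParams()) {
  stopifnot(is(rec, "AudioRecording"), is(params, "CleaningParams"))
  x <- rec@samples
  n <- length(x)
  sr <- rec@sampleRate

  p2 <- x^2
  env <- runningMean(p2, params@envelopeWindow * sr)
  env[env < .Machine$double.eps^2] <- .Machine$double.eps^2
  env <- sqrt(env)
  cross <- which(abs(x) > params@spikeFactor * env)
  if (length(cross) == 0)
    return(data.frame(start = integer(), end = integer()))

  pad <- max(1L, as.integer(round(0.001 * sr)))
  gap <- max(1L, as.integer(round(0.005 * sr)))
  grp <- cumsum(c(1L, diff(cross) > gap))
  lo <- tapply(cross, grp, min)
  hi <- tapply(cross, grp, max)
  start <- pmax(1L, as.integer(lo) - pad)
  end <- pmin(n, as.integer(hi) + pad) + 1L   # half-open

  # merge padded intervals that now touch/overlap
  if (length(start) > 1) {
    keepRow <- rep(TRUE, length(start))
    for (i in seq_along(start)[-1]) {
      j <- max(which(keepRow[seq_len(i - 1)]))
      if (start[i] <= end[j]) {
        end[j] <- max(end[j], end[i])
        keepRow[i] <- FALSE
      }
    }
    start <- start[keepRow]
    end <- end[keepRow]
  }

  fast <- runningMean(p2, params@confirmWindow * sr)
  fast[fast < 0] <- 0
  fast <- sqrt(fast)
  keep <- vapply(seq_along(start), function(i) {
    idx <- start[i]:(end[i] - 1L)
    any(fast[idx] > params@confirmFactor * env[idx])
  }, logical(1))

  data.frame(start = start[keep], end = end[keep])
}

#' Remove snapping-shrimp transients
#'
#' Replaces samples inside the intervals from \code{\link{detectSnaps}} with
#' the centered moving average of the surrounding non-snap samples (window
#' \code{replacementWindow}); all other samples are bit-identical to the
#' input.
#'
#' Detection and excision iterate together: a dense snap cluster inflates
#' the first-pass envelope and can hide a weaker neighbour, which becomes
#' visible once the cluster is excised, so passes repeat (up to
#' \code{maxPasses}) until no further snaps are found.  The fixpoint makes
#' the operation idempotent.
#'
#' @inheritParams detectSnaps
#' @param maxPasses maximum detect/excise passes (default 4; scenes
#'   typically converge in 1-2).
#' @return A cleaned \code{AudioRecording} of identical length.
#' @export
removeSnaps <- function(rec, params = cleaningParams(), maxPasses = 4) {
  n <- length(rec@samples)
  for (pass in seq_len(maxPasses)) {
    iv <- detectSnaps(rec, params)
    if (nrow(iv) == 0) return(rec)
    if (nrow(iv) == 1 && iv$start[1] <= 1 && iv$end[1] >= n + 1) {
      warning("detected snap interval spans the entire file; returning input unchanged")
      return(rec)
    }
    x <- rec@samples
    mask <- logical(n)
    for (i in seq_len(nrow(iv))) mask[iv$start[i]:(iv$end[i] - 1L)] <- TRUE

    w <- params@replacementWindow * rec@sampleRate
    xKeep <- x
    xKeep[mask] <- 0
    num <- runningMean(xKeep, w)
    den <- runningMean(as.numeric(!mask), w)
    fill <- num / den
    fill[den <= 0] <- 0
    x[mask] <- fill[mask]
    rec <- initialize(rec, samples = x)
  }
  rec
}
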