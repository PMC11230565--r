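# Stage 1: framed broadband SPL with hydrophone calibration, the file-wide
# median, and candidate-segment gating.
#
# Per frame, the Hann-tapered single-sided power spectrum
# Pss(f) = 2 |DFT(y w)/ (N mean(w))|^2 (DC and Nyquist bins not doubled) is
# summed over the band and converted to dB re 1 uPa:
#   SPL = 10 log10( sum_band Pss / B ) - S,
# where B is the window power-bandwidth factor (1.5 for Hann) and S the
# calibration correction.  The window is amplitude-normalized by its
# coherent gain, so with the B division a sine of amplitude A measures
# 10 log10(A^2/2) and white noise measures its mean-square power.

#' Calibration correction factor
#'
#' \eqn{S = M_h + G + 20\log_{10}(1/V_{ADC})} in dB; subtracting S converts
#' band power in ADC-normalized units to dB re 1 uPa.
#'
#' @param cal a \code{\link{calibrationSpec}}.
#' @return S in dB.
#' @examples
#' correctionFactor(calibrationSpec(-185, 20, 1))  # -165
#' @export
correctionFactor <- function(cal) {
  stopifnot(is(cal, "CalibrationSpec"))
  cal@sensitivity + cal@gain + 20 * log10(1 / cal@vAdc)
}

# Shared core: band-summed single-sided power for a matrix of frames
# (frames in columns), before the B division and S subtraction.
frameBandPower <- function(frames, sampleRate, bandLow, bandHigh) {
  L <- nrow(frames)
  w <- hannWindow(L)
  Y <- stats::mvfft(frames * w)
  nb <- L %/% 2L + 1L
  P <- (Mod(Y[seq_len(nb), , drop = FALSE]) / (L * mean(w)))^2
  mult <- rep(2, nb)
  mult[1] <- 1
  if (L %% 2L == 0L) mult[nb] <- 1
  P <- P * mult
  f <- (seq_len(nb) - 1) * sampleRate / L
  sel <- f >= bandLow & f <= min(bandHigh, sampleRate / 2)
  colSums(P[sel, , drop = FALSE])
}

#' Broadband SPL of a single frame
#'
#' @param frame numeric amplitude vector (>= 2 samples).
#' @param sampleRate sampling rate in Hz.
#' @param cal a \code{\link{calibrationSpec}}.
#' @param params an \code{\link{splParams}} (band and window settings; the
#'   frame length is taken from \code{frame} itself).
#' @return SPL in dB re 1 uPa; \code{-Inf} with a warning for an all-zero
#'   frame.
#' @export
frameSpl <- function(frame, sampleRate, cal = calibrationSpec(),
                     params = splParams()) {
  if (length(frame) < 2) stop("frame must contain at least 2 samples")
  tot <- frameBandPower(matrix(frame, ncol = 1), sampleRate,
                        params@bandLow, params@bandHigh)
  if (tot == 0) {
    warning("all-zero frame; SPL is -Inf")
    return(-Inf)
  }
  10 * log10(tot / params@bandwidthFactor) - correctionFactor(cal)
}

#' Framed SPL series with file-wide median
#'
#' Cuts the recording into consecutive non-overlapping frames of
#' \code{frameLength} seconds (a final partial frame is dropped), computes
#' each frame's band SPL and the median over all frames of the file.
#'
#' @param rec an \code{\link{audioRecording}} at least one frame long.
#' @inheritParams frameSpl
#' @return A \code{\link{FrameEnergySeries-class}}.
#' @export
splSeries <- function(rec, cal = calibrationSpec(), params = splParams()) {
  stopifnot(is(rec, "AudioRecording"), is(params, "SplParams"))
  sr <- rec@sampleRate
  L <- as.integer(round(params@frameLength * sr))
  if (L < 2) stop("frameLength too short for this sample rate")
  n <- length(rec@samples)
  nf <- n %/% L
  if (nf < 1) stop("recording shorter than one SPL frame")

  S <- correctionFactor(cal)
  B <- params@bandwidthFactor
  splv <- numeric(nf)
  chunk <- max(1L, as.integer(2^21 %/% L))   # bound working memory
  for (i0 in seq.int(1L, nf, by = chunk)) {
    i1 <- min(nf, i0 + chunk - 1L)
    frames <- matrix(rec@samples[((i0 - 1L) * L + 1L):(i1 * L)], nrow = L)
    splv[i0:i1] <- frameBandPower(frames, sr, params@bandLow, params@bandHigh)
  }
  if (any(splv == 0)) warning("all-zero frame(s); SPL set to -Inf")
  splv <- 10 * log10(splv / B) - S

  new("FrameEnergySeries",
      frameCenters = (seq_len(nf) - 0.5) * L / sr,
      spl = splv, splMedian = stats::median(splv),
      frameLength = L / sr, sourceId = rec@sourceId)
}

#' Median-gated candidate segments
#'
#' Marks frames with SPL strictly above the file median plus \code{margin}
#' dB, merges consecutive marked frames (bridging unmarked gaps of at most
#' \code{mergeGap} seconds) into segments, and discards segments shorter
#' than \code{minDuration}.  \code{margin = 0} reproduces the literal
#' above-the-median gate; the 3 dB default suppresses the ~half of noise
#' frames that sit above the median while keeping any burst worth
#' classifying.
#'
#' @param series a \code{\link{FrameEnergySeries-class}}.
#' @param margin gating margin in dB above the median (default 3).
#' @param minDuration minimum segment duration in seconds (default 1).
#' @param mergeGap maximum bridged gap in seconds (default 1).
#' @return data.frame with columns \code{start}, \code{end} (segment bounds
#'   at frame edges, seconds), \code{peakTime} (center of the loudest frame,
#'   earliest on ties) and \code{peakExcess} (dB above the median).  Zero
#'   rows when nothing is gated.
#' @export
candidateSegments <- function(series, margin = 3, minDuration = 1,
                              mergeGap = 1) {
  stopifnot(is(series, "FrameEnergySeries"))
  fl <- series@frameLength
  marked <- which(series@spl > series@splMedian + margin)
  empty <- data.frame(start = numeric(), end = numeric(),
                      peakTime = numeric(), peakExcess = numeric())
  if (length(marked) == 0) return(empty)

  gapFrames <- floor(mergeGap / fl + 1e-9)
  grp <- cumsum(c(1L, (diff(marked) - 1L) > gapFrames))
  out <- lapply(split(marked, grp), function(fr) {
    first <- min(fr); last <- max(fr)
    start <- (first - 1) * fl
    end <- last * fl
    if (end - start < minDuration) return(NULL)
    span <- first:last
    pk <- span[which.max(series@spl[span])]
    data.frame(start = start, end = end,
               peakTime = series@frameCenters[pk],
               peakExcess = max(series@spl[span]) - series@splMedian)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) empty else { rownames(out) <- NULL; out }
}
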