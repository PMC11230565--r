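# S4 class definitions for the deep-scanning pipeline.

#' AudioRecording: a calibrated mono waveform
#'
#' The unit every pipeline stage consumes: a vector of dimensionless
#' ADC-normalized amplitudes in \[-1, 1\], the sample rate in Hz, a source
#' identifier (usually the file basename) and an optional start timestamp.
#' Conversion to absolute pressure happens only inside the energy module via
#' the calibration correction (see \code{\link{correctionFactor}}), so
#' amplitudes stay dimensionless everywhere else.
#'
#' @slot samples numeric vector of amplitudes, finite, nominally in \[-1, 1\].
#' @slot sampleRate sampling rate in Hz (> 0).
#' @slot sourceId character scalar identifying the source file/station.
#' @slot startTime optional \code{POSIXct} recording start time (NA if unknown).
#' @exportClass AudioRecording
setClass("AudioRecording",
  representation(samples = "numeric", sampleRate = "numeric",
                 sourceId = "character", startTime = "POSIXct"),
  validity = function(object) {
    msg <- character()
    if (length(object@sampleRate) != 1 || !is.finite(object@sampleRate) ||
        object@sampleRate <= 0)
      msg <- c(msg, "sampleRate must be a single positive number")
    if (length(object@samples) == 0)
      msg <- c(msg, "samples must be non-empty")
    if (anyNA(object@samples) || any(!is.finite(object@samples)))
      msg <- c(msg, "samples must be finite")
    if (length(object@sourceId) != 1)
      msg <- c(msg, "sourceId must be a single string")
    if (length(msg)) msg else TRUE
  })

#' Construct an AudioRecording
#'
#' @param samples numeric amplitude vector (ADC-normalized, \[-1, 1\]).
#' @param sampleRate sampling rate in Hz.
#' @param sourceId source identifier.
#' @param startTime optional POSIXct start time.
#' @return An \code{AudioRecording}.
#' @examples
#' rec <- audioRecording(sin(2 * pi * 100 * seq(0, 1, by = 1 / 8000)), 8000)
#' duration(rec)
#' @export
audioRecording <- function(samples, sampleRate, sourceId = "<memory>",
                           startTime = as.POSIXct(NA)) {
  new("AudioRecording", samples = as.numeric(samples),
      sampleRate = as.numeric(sampleRate), sourceId = as.character(sourceId),
      startTime = startTime)
}

#' CalibrationSpec: hydrophone calibration constants
#'
#' Holds the constants of the calibration correction
#' \eqn{S = M_h + G + 20 \log_{10}(1/V_{ADC})}: hydrophone sensitivity
#' \eqn{M_h} (dB re V/uPa), system gain \eqn{G} (dB), and the zero-to-peak
#' voltage of the analogue-to-digital converter \eqn{V_{ADC}} (volts).
#' The default sensitivity is -185.5 dB re V/uPa with 20 dB gain and a 1 V
#' converter, matching a typical estuarine DSG recorder configuration.
#'
#' @slot sensitivity hydrophone sensitivity in dB re V/uPa.
#' @slot gain system gain in dB.
#' @slot vAdc ADC zero-to-peak voltage in volts (> 0).
#' @exportClass CalibrationSpec
setClass("CalibrationSpec",
  representation(sensitivity = "numeric", gain = "numeric", vAdc = "numeric"),
  validity = function(object) {
    if (length(object@vAdc) != 1 || !is.finite(object@vAdc) || object@vAdc <= 0)
      return("vAdc must be a single positive voltage")
    TRUE
  })

#' @rdname CalibrationSpec-class
#' @param sensitivity hydrophone sensitivity, dB re V/uPa.
#' @param gain system gain, dB.
#' @param vAdc ADC zero-to-peak voltage, volts.
#' @return A \code{CalibrationSpec}.
#' @export
calibrationSpec <- function(sensitivity = -185.5, gain = 20, vAdc = 1) {
  new("CalibrationSpec", sensitivity = sensitivity, gain = gain, vAdc = vAdc)
}

#' CleaningParams: snapping-shrimp removal parameters
#'
#' Snaps are detected as samples exceeding \code{spikeFactor} times the local
#' RMS envelope (computed over \code{envelopeWindow} seconds), confirmed by
#' requiring the fast millisecond-scale RMS (over \code{confirmWindow}) to
#' exceed \code{confirmFactor} times the slow envelope -- an isolated Gaussian
#' tail sample passes the amplitude test roughly once per 16 k samples, but
#' carries no millisecond-scale energy, which is what physically defines a
#' snap.  Detected samples are replaced by the centered moving average of the
#' surrounding non-snap samples over \code{replacementWindow} seconds.
#'
#' @slot envelopeWindow slow RMS envelope window, seconds.
#' @slot spikeFactor amplitude threshold as a multiple of the envelope.
#' @slot replacementWindow moving-average fill window, seconds.
#' @slot confirmWindow fast RMS window for energy confirmation, seconds.
#' @slot confirmFactor fast-RMS/envelope ratio required to keep an interval.
#' @exportClass CleaningParams
setClass("CleaningParams",
  representation(envelopeWindow = "numeric", spikeFactor = "numeric",
                 replacementWindow = "numeric", confirmWindow = "numeric",
                 confirmFactor = "numeric"),
  validity = function(object) {
    v <- c(object@envelopeWindow, object@spikeFactor,
           object@replacementWindow, object@confirmWindow,
           object@confirmFactor)
    if (any(!is.finite(v)) || any(v <= 0))
      return("all cleaning parameters must be positive")
    TRUE
  })

#' @rdname CleaningParams-class
#' @param envelopeWindow,spikeFactor,replacementWindow,confirmWindow,confirmFactor
#'   see slots.
#' @return A \code{CleaningParams}.
#' @export
cleaningParams <- function(envelopeWindow = 0.05, spikeFactor = 4,
                           replacementWindow = 0.05, confirmWindow = 0.001,
                           confirmFactor = 2) {
  new("CleaningParams", envelopeWindow = envelopeWindow,
      spikeFactor = spikeFactor, replacementWindow = replacementWindow,
      confirmWindow = confirmWindow, confirmFactor = confirmFactor)
}

#' SplParams: framed broadband SPL parameters
#'
#' Controls stage 1: the waveform is cut into consecutive non-overlapping
#' frames of \code{frameLength} seconds, each frame is Hann-tapered and its
#' single-sided power spectrum summed over \[\code{bandLow}, \code{bandHigh}\]
#' Hz; the summed power is divided by the window bandwidth factor
#' \code{bandwidthFactor} (1.5 for Hann) before conversion to dB re 1 uPa.
#'
#' @slot frameLength frame length in seconds (default 0.5).
#' @slot bandLow low band edge, Hz (default 1, excluding DC).
#' @slot bandHigh high band edge, Hz (default 40000; clamped to Nyquist).
#' @slot window taper name; only \code{"hann"} is supported.
#' @slot bandwidthFactor window power bandwidth B (1.5 for Hann).
#' @exportClass SplParams
setClass("SplParams",
  representation(frameLength = "numeric", bandLow = "numeric",
                 bandHigh = "numeric", window = "character",
                 bandwidthFactor = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@frameLength <= 0) msg <- c(msg, "frameLength must be positive")
    if (object@bandLow < 0 || object@bandLow >= object@bandHigh)
      msg <- c(msg, "need 0 <= bandLow < bandHigh")
    if (!identical(object@window, "hann"))
      msg <- c(msg, "only the 'hann' window is supported")
    if (object@bandwidthFactor <= 0)
      msg <- c(msg, "bandwidthFactor must be positive")
    if (length(msg)) msg else TRUE
  })

#' @rdname SplParams-class
#' @param frameLength,bandLow,bandHigh,window,bandwidthFactor see slots.
#' @return An \code{SplParams}.
#' @export
splParams <- function(frameLength = 0.5, bandLow = 1, bandHigh = 40000,
                      window = "hann", bandwidthFactor = 1.5) {
  new("SplParams", frameLength = frameLength, bandLow = bandLow,
      bandHigh = bandHigh, window = window, bandwidthFactor = bandwidthFactor)
}

#' FrameEnergySeries: per-frame SPL with the file-wide median
#'
#' The gating surface of stage 1: one SPL value (dB re 1 uPa) per frame plus
#' the median over the whole file.  The median is always over the entire
#' file, never a running median.
#'
#' @slot frameCenters frame center times, seconds.
#' @slot spl per-frame SPL, dB re 1 uPa (-Inf for all-zero frames).
#' @slot splMedian median SPL of the whole file.
#' @slot frameLength frame length in seconds.
#' @slot sourceId originating recording id.
#' @exportClass FrameEnergySeries
setClass("FrameEnergySeries",
  representation(frameCenters = "numeric", spl = "numeric",
                 splMedian = "numeric", frameLength = "numeric",
                 sourceId = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@frameCenters) != length(object@spl))
      msg <- c(msg, "frameCenters and spl must have equal length")
    med <- stats::median(object@spl)
    same <- (is.finite(med) && is.finite(object@splMedian) &&
             abs(med - object@splMedian) < 1e-9) ||
            identical(med, object@splMedian)
    if (!same) msg <- c(msg, "splMedian must equal median(spl)")
    if (length(msg)) msg else TRUE
  })

#' FeatureParams: spectrogram feature-window geometry
#'
#' A feature window is a fixed-size time-by-frequency patch of the
#' log-magnitude spectrogram: \code{deltaT} seconds wide, restricted to
#' \[\code{fLow}, \code{fHigh}\] Hz, resampled to a \code{gridTime} x
#' \code{gridFreq} grid and standardized within the window.  Defaults follow
#' the detector's working profile: 5.5 s windows over 800-10000 Hz (the band
#' above fish chorusing and below the storage-hungry high frequencies), on a
#' 32 x 32 grid feeding a small dense network.
#'
#' @slot deltaT window duration, seconds.
#' @slot fLow,fHigh frequency band, Hz (fHigh is clamped to Nyquist at use).
#' @slot fftLength STFT length, samples.
#' @slot hop STFT hop, samples.
#' @slot gridTime,gridFreq output grid resolution.
#' @exportClass FeatureParams
setClass("FeatureParams",
  representation(deltaT = "numeric", fLow = "numeric", fHigh = "numeric",
                 fftLength = "numeric", hop = "numeric",
                 gridTime = "numeric", gridFreq = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@deltaT <= 0) msg <- c(msg, "deltaT must be positive")
    if (object@fLow >= object@fHigh) msg <- c(msg, "need fLow < fHigh")
    if (object@gridTime < 8 || object@gridFreq < 8)
      msg <- c(msg, "grid dimensions must be >= 8")
    if (object@fftLength < 8 || object@hop < 1)
      msg <- c(msg, "invalid STFT geometry")
    if (length(msg)) msg else TRUE
  })

#' @rdname FeatureParams-class
#' @param deltaT,fLow,fHigh,fftLength,hop,gridTime,gridFreq see slots.
#' @return A \code{FeatureParams}.
#' @export
featureParams <- function(deltaT = 5.5, fLow = 800, fHigh = 10000,
                          fftLength = 2048, hop = 1024,
                          gridTime = 32, gridFreq = 32) {
  new("FeatureParams", deltaT = deltaT, fLow = fLow, fHigh = fHigh,
      fftLength = fftLength, hop = hop, gridTime = gridTime,
      gridFreq = gridFreq)
}

#' FeatureWindow: one classifier input patch
#'
#' @slot values gridTime x gridFreq matrix of standardized log-spectrogram
#'   energy (rows = time, columns = frequency).
#' @slot centerTime window center within the source recording, seconds.
#' @slot sourceId originating recording id.
#' @slot label optional class label (1 vessel, 0 non-vessel, NA unknown).
#' @exportClass FeatureWindow
setClass("FeatureWindow",
  representation(values = "matrix", centerTime = "numeric",
                 sourceId = "character", label = "integer"),
  validity = function(object) {
    if (anyNA(object@values) || any(!is.finite(object@values)))
      return("feature values must be finite")
    TRUE
  })

#' TrainingSet: labeled feature windows
#'
#' Parallel lists of feature windows and binary targets (1 = vessel,
#' 0 = non-vessel); both classes must be present before training.
#'
#' @slot features list of \code{FeatureWindow}.
#' @slot targets integer vector of 0/1 targets, same length.
#' @exportClass TrainingSet
setClass("TrainingSet",
  representation(features = "list", targets = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@features) != length(object@targets))
      msg <- c(msg, "features and targets must have equal length")
    if (!all(object@targets %in% c(0L, 1L)))
      msg <- c(msg, "targets must be 0 or 1")
    if (length(msg)) msg else TRUE
  })

#' @rdname TrainingSet-class
#' @param features list of \code{FeatureWindow}.
#' @param targets integer 0/1 vector.
#' @return A \code{TrainingSet}.
#' @export
trainingSet <- function(features, targets) {
  new("TrainingSet", features = features, targets = as.integer(targets))
}

#' ClassifierModel: a small dense feed-forward network
#'
#' Hidden layers use tanh activations; the single output neuron is a sigmoid
#' giving a vessel score in \[0, 1\].  The default architecture is three
#' hidden layers of 10, 8 and 6 neurons.
#'
#' @slot inputDim flattened feature-window length.
#' @slot layerSizes hidden-layer widths.
#' @slot weights list of weight matrices (out x in per layer, output last).
#' @slot biases list of bias vectors, parallel to \code{weights}.
#' @slot activation hidden activation name ("tanh").
#' @slot trainingMeta list of training metadata (seed, epochs, loss history).
#' @exportClass ClassifierModel
setClass("ClassifierModel",
  representation(inputDim = "numeric", layerSizes = "numeric",
                 weights = "list", biases = "list", activation = "character",
                 trainingMeta = "list"),
  validity = function(object) {
    dims <- c(object@inputDim, object@layerSizes, 1)
    nl <- length(dims) - 1
    if (length(object@weights) != nl || length(object@biases) != nl)
      return("weights/biases inconsistent with layer sizes")
    for (l in seq_len(nl)) {
      if (!all(dim(object@weights[[l]]) == c(dims[l + 1], dims[l])))
        return(sprintf("weight matrix %d has wrong shape", l))
      if (length(object@biases[[l]]) != dims[l + 1])
        return(sprintf("bias vector %d has wrong length", l))
    }
    TRUE
  })

#' FileResult: per-file scan outcome
#'
#' @slot sourceId scanned recording id.
#' @slot vesselPresent TRUE if any candidate was classified as a vessel.
#' @slot detections data.frame with one row per candidate segment
#'   (eventTime, score, decision, segStart, segEnd, peakExcess).
#' @slot splMedian file-wide median SPL, dB re 1 uPa.
#' @exportClass FileResult
setClass("FileResult",
  representation(sourceId = "character", vesselPresent = "logical",
                 detections = "data.frame", splMedian = "numeric"),
  validity = function(object) {
    if (nrow(object@detections) > 0 &&
        !identical(object@vesselPresent, any(object@detections$decision)))
      return("vesselPresent must be the OR of detection decisions")
    TRUE
  })

#' EvaluationResult: per-file accuracy against manual labels
#'
#' Errors are symmetric per-file disagreements (a flagged file without a
#' vessel, or an unflagged file with one); the accuracy is
#' \eqn{\rho = (N - n_\epsilon) / N}.
#'
#' @slot nTotal number of evaluated files N.
#' @slot nError number of erroneous files.
#' @slot falsePositives,falseNegatives error decomposition.
#' @slot rho detection accuracy, exact (N - nError)/N.
#' @exportClass EvaluationResult
setClass("EvaluationResult",
  representation(nTotal = "integer", nError = "integer",
                 falsePositives = "integer", falseNegatives = "integer",
                 rho = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@nError != object@falsePositives + object@falseNegatives)
      msg <- c(msg, "nError must equal falsePositives + falseNegatives")
    if (object@nTotal > 0 &&
        object@rho != (object@nTotal - object@nError) / object@nTotal)
      msg <- c(msg, "rho must equal (nTotal - nError)/nTotal")
    if (object@rho < 0 || object@rho > 1) msg <- c(msg, "rho out of [0, 1]")
    if (length(msg)) msg else TRUE
  })

#' SELMetrics: per-event sound-exposure summary
#'
#' Peak and mean SPL excess over the file median within a candidate segment,
#' and the trapezoidal area between the SPL curve and the median line
#' (clamped below at zero) as the SEL proxy in dB s.
#'
#' @slot peakDifference max SPL minus median within the segment, dB.
#' @slot meanDifference mean of above-median SPL minus median, dB.
#' @slot areaSize trapezoidal above-median area, dB s.
#' @slot start,end segment bounds, seconds.
#' @exportClass SELMetrics
setClass("SELMetrics",
  representation(peakDifference = "numeric", meanDifference = "numeric",
                 areaSize = "numeric", start = "numeric", end = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@meanDifference < 0 || object@areaSize < 0)
      msg <- c(msg, "SEL metrics must be non-negative")
    if (object@peakDifference < object@meanDifference)
      msg <- c(msg, "peakDifference must be >= meanDifference")
    if (length(msg)) msg else TRUE
  })

#' SceneSpec: synthetic estuarine soundscape specification
#'
#' Describes one simulated 2-minute station recording: Gaussian broadband
#' background at \code{backgroundRms}, Poisson snapping-shrimp clicks
#' (millisecond damped sinusoids at \code{snapAmplitudeFactor} times the
#' background RMS), an optional slowly amplitude-modulated fish chorus in
#' \code{chorus$band} Hz, and vessel events.  Event kinds are
#' \code{burst_narrow}/\code{burst_wide} (broadband bursts; durations sampled
#' from truncated normals with means 5.9 s / 15.9 s and SDs 2.1 s / 6.6 s
#' when not fixed), \code{variable_broadband} (long, < 25 kHz) and
#' \code{low_frequency} (< 1 kHz) confounders.  Event \code{level} is dB
#' above the background broadband RMS.
#'
#' @slot duration scene duration, seconds.
#' @slot sampleRate sampling rate, Hz.
#' @slot backgroundRms background amplitude RMS (ADC-normalized units).
#' @slot snapRate snaps per second (Poisson).
#' @slot snapAmplitudeFactor snap peak amplitude as multiple of background RMS.
#' @slot chorus list(enabled, band, level, modDepth, modPeriod).
#' @slot events data.frame(kind, start, duration, level); NA duration/level
#'   are sampled/defaulted at simulation time.
#' @slot seed RNG seed making the scene fully reproducible.
#' @exportClass SceneSpec
setClass("SceneSpec",
  representation(duration = "numeric", sampleRate = "numeric",
                 backgroundRms = "numeric", snapRate = "numeric",
                 snapAmplitudeFactor = "numeric", chorus = "list",
                 events = "data.frame", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@duration <= 0 || object@sampleRate <= 0)
      msg <- c(msg, "duration and sampleRate must be positive")
    if (object@backgroundRms <= 0)
      msg <- c(msg, "backgroundRms must be positive")
    if (object@snapRate < 0) msg <- c(msg, "snapRate must be >= 0")
    ev <- object@events
    if (nrow(ev) > 0) {
      if (!all(c("kind", "start", "duration", "level") %in% names(ev)))
        msg <- c(msg, "events needs columns kind, start, duration, level")
      else {
        if (any(ev$start < 0 | ev$start >= object@duration))
          msg <- c(msg, "event starts must lie within [0, duration)")
        bad <- !ev$kind %in% c("burst_narrow", "burst_wide",
                               "variable_broadband", "low_frequency")
        if (any(bad)) msg <- c(msg, "unknown event kind")
      }
    }
    if (length(msg)) msg else TRUE
  })

#' @rdname SceneSpec-class
#' @param duration,sampleRate,backgroundRms,snapRate,snapAmplitudeFactor,seed
#'   see slots.
#' @param chorusEnabled,chorusBand,chorusLevel,chorusModDepth,chorusModPeriod
#'   fish-chorus settings: band (Hz), level (dB above background), slow
#'   sinusoidal amplitude-modulation depth and period (seconds).
#' @param events data.frame(kind, start, duration, level).
#' @return A \code{SceneSpec}.
#' @export
sceneSpec <- function(duration = 120, sampleRate = 80000,
                      backgroundRms = 0.01, snapRate = 5,
                      snapAmplitudeFactor = 8,
                      chorusEnabled = FALSE, chorusBand = c(50, 800),
                      chorusLevel = 6, chorusModDepth = 0.6,
                      chorusModPeriod = 30,
                      events = emptyEvents(), seed = 1L) {
  new("SceneSpec", duration = duration, sampleRate = sampleRate,
      backgroundRms = backgroundRms, snapRate = snapRate,
      snapAmplitudeFactor = snapAmplitudeFactor,
      chorus = list(enabled = isTRUE(chorusEnabled), band = chorusBand,
                    level = chorusLevel, modDepth = chorusModDepth,
                    modPeriod = chorusModPeriod),
      events = events, seed = as.integer(seed))
}

#' @rdname SceneSpec-class
#' @export
emptyEvents <- function() {
  data.frame(kind = character(), start = numeric(), duration = numeric(),
             level = numeric(), stringsAsFactors = FALSE)
}

#' @rdname SceneSpec-class
#' @param kind event kind (\code{"burst_narrow"}, \code{"burst_wide"},
#'   \code{"variable_broadband"}, \code{"low_frequency"}).
#' @param start event start, seconds.
#' @return \code{vesselEvent}: a one-row events data.frame.
#' @export
vesselEvent <- function(kind, start, duration = NA_real_, level = NA_real_) {
  data.frame(kind = kind, start = start, duration = duration, level = level,
             stringsAsFactors = FALSE)
}
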