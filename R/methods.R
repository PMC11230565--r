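# Accessor and show methods.

#' @describeIn AudioRecording-class amplitude vector.
#' @param x an object.
#' @export
setMethod("samples", "AudioRecording", function(x) x@samples)

#' @describeIn AudioRecording-class sampling rate in Hz.
#' @export
setMethod("sampleRate", "AudioRecording", function(x) x@sampleRate)

#' @describeIn AudioRecording-class source identifier.
#' @export
setMethod("sourceId", "AudioRecording", function(x) x@sourceId)

#' @describeIn AudioRecording-class recording start time (possibly NA).
#' @export
setMethod("startTime", "AudioRecording", function(x) x@startTime)

#' @describeIn AudioRecording-class duration in seconds.
#' @export
setMethod("duration", "AudioRecording",
          function(x) length(x@samples) / x@sampleRate)

setMethod("show", "AudioRecording", function(object) {
  cat(sprintf("AudioRecording '%s': %.3f s at %g Hz (%d samples)\n",
              object@sourceId, duration(object), object@sampleRate,
              length(object@samples)))
  if (!is.na(object@startTime))
    cat("  start:", format(object@startTime), "\n")
})

#' @describeIn FrameEnergySeries-class per-frame SPL values (dB re 1 uPa).
#' @param x an object.
#' @export
setMethod("spl", "FrameEnergySeries", function(x) x@spl)

#' @describeIn FrameEnergySeries-class file-wide median SPL.
#' @export
setMethod("splMedian", "FrameEnergySeries", function(x) x@splMedian)

#' @describeIn FrameEnergySeries-class frame center times in seconds.
#' @export
setMethod("frameCenters", "FrameEnergySeries", function(x) x@frameCenters)

#' @describeIn FrameEnergySeries-class number of frames.
#' @export
setMethod("length", "FrameEnergySeries", function(x) length(x@spl))

setMethod("show", "FrameEnergySeries", function(object) {
  cat(sprintf(
    "FrameEnergySeries '%s': %d frames of %g s, median SPL %.1f dB re 1 uPa\n",
    object@sourceId, length(object@spl), object@frameLength,
    object@splMedian))
})

#' Export a frame-energy series as a data.frame
#'
#' @param x a \code{FrameEnergySeries}.
#' @param row.names,optional,... ignored (base generic signature).
#' @return data.frame with columns \code{frame_center_s}, \code{spl_db}.
#' @export
as.data.frame.FrameEnergySeries <- function(x, row.names = NULL,
                                            optional = FALSE, ...) {
  data.frame(frame_center_s = x@frameCenters, spl_db = x@spl)
}
setMethod("as.data.frame", "FrameEnergySeries",
          as.data.frame.FrameEnergySeries)

#' @describeIn FeatureWindow-class standardized value matrix (time x freq).
#' @param x an object.
#' @export
setMethod("featureValues", "FeatureWindow", function(x) x@values)

setMethod("show", "FeatureWindow", function(object) {
  cat(sprintf(
    "FeatureWindow from '%s' at %.2f s: %d x %d (time x freq), label %s\n",
    object@sourceId, object@centerTime, nrow(object@values),
    ncol(object@values),
    if (is.na(object@label)) "unknown" else object@label))
})

#' @describeIn TrainingSet-class number of feature windows.
#' @param x an object.
#' @export
setMethod("length", "TrainingSet", function(x) length(x@features))

setMethod("show", "TrainingSet", function(object) {
  cat(sprintf("TrainingSet: %d windows (%d vessel, %d non-vessel)\n",
              length(object@features), sum(object@targets == 1L),
              sum(object@targets == 0L)))
})

setMethod("show", "ClassifierModel", function(object) {
  cat(sprintf("ClassifierModel: %d -> %s -> 1 (%s hidden, sigmoid output)\n",
              object@inputDim, paste(object@layerSizes, collapse = " -> "),
              object@activation))
  if (!is.null(object@trainingMeta$epochsRun))
    cat(sprintf("  trained %d epochs, final training loss %.4g\n",
                object@trainingMeta$epochsRun,
                utils::tail(object@trainingMeta$lossHistory, 1)))
})

setMethod("show", "FileResult", function(object) {
  cat(sprintf("FileResult '%s': vessel %s, %d candidate(s), median SPL %.1f dB\n",
              object@sourceId, if (object@vesselPresent) "PRESENT" else "absent",
              nrow(object@detections), object@splMedian))
})

setMethod("show", "EvaluationResult", function(object) {
  cat(sprintf(
    "EvaluationResult: rho = %.4f (%d/%d correct; %d FP, %d FN)\n",
    object@rho, object@nTotal - object@nError, object@nTotal,
    object@falsePositives, object@falseNegatives))
})

setMethod("show", "SELMetrics", function(object) {
  cat(sprintf(
    "SELMetrics [%.1f, %.1f] s: peak %.2f dB, mean %.2f dB, area %.2f dB s\n",
    object@start, object@end, object@peakDifference, object@meanDifference,
    object@areaSize))
})

setMethod("show", "SceneSpec", function(object) {
  cat(sprintf(
    "SceneSpec: %g s at %g Hz, background RMS %g, %g snaps/s, chorus %s, %d event(s), seed %d\n",
    object@duration, object@sampleRate, object@backgroundRms, object@snapRate,
    if (isTRUE(object@chorus$enabled)) "on" else "off", nrow(object@events),
    object@seed))
})
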