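# Generics for accessors and core verbs.

#' @export
setGeneric("samples", function(x) standardGeneric("samples"))
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))
#' @export
setGeneric("sourceId", function(x) standardGeneric("sourceId"))
#' @export
setGeneric("startTime", function(x) standardGeneric("startTime"))
#' @export
setGeneric("duration", function(x) standardGeneric("duration"))
#' @export
setGeneric("spl", function(x) standardGeneric("spl"))
#' @export
setGeneric("splMedian", function(x) standardGeneric("splMedian"))
#' @export
setGeneric("frameCenters", function(x) standardGeneric("frameCenters"))
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))
#' @export
setGeneric("predictScore", function(model, newdata, ...)
  standardGeneric("predictScore"))
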