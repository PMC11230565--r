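# The deep-scanning orchestration: clean -> framed SPL + median gate ->
# feature windows at candidate peaks -> classifier -> per-file decision,
# over single files and batches.

#' Scan configuration
#'
#' Bundles the per-stage parameter objects with the scan-level knobs.
#' Segments longer than one feature window are tiled with windows every
#' deltaT/2 and score the maximum -- a single window centered at the SPL
#' peak covers narrow bursts, tiling covers wide ones.
#'
#' @param cleaning a \code{\link{cleaningParams}}.
#' @param energy an \code{\link{splParams}}.
#' @param features a \code{\link{featureParams}}.
#' @param margin,minDuration,mergeGap gating controls, see
#'   \code{\link{candidateSegments}}.
#' @param threshold decision threshold on the classifier score (default 0.5).
#' @param clean logical; run snap removal before scanning (default TRUE).
#' @return A list of class \code{ScanConfig}.
#' @export
scanConfig <- function(cleaning = cleaningParams(), energy = splParams(),
                       features = featureParams(), margin = 3,
                       minDuration = 1, mergeGap = 1, threshold = 0.5,
                       clean = TRUE) {
  structure(list(cleaning = cleaning, energy = energy, features = features,
                 margin = margin, minDuration = minDuration,
                 mergeGap = mergeGap, threshold = threshold,
                 clean = isTRUE(clean)),
            class = "ScanConfig")
}

#' Read a scan configuration from YAML
#'
#' Recognized sections \code{cleaning}, \code{energy}, \code{features} and
#' \code{scanner} hold the arguments of the corresponding constructors
#' (\code{scanner} holds margin/minDuration/mergeGap/threshold/clean);
#' omitted entries keep their defaults.
#'
#' @param path YAML file path.
#' @return A \code{ScanConfig}.
#' @export
readScanConfig <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$cleaning)) args$cleaning <- do.call(cleaningParams, y$cleaning)
  if (!is.null(y$energy)) args$energy <- do.call(splParams, y$energy)
  if (!is.null(y$features)) args$features <- do.call(featureParams, y$features)
  do.call(scanConfig, c(args, y$scanner))
}

#' Scan one recording for vessel noise
#'
#' Runs the full pipeline in order: optional snap cleaning, framed SPL with
#' file-wide median, median-gated candidate segments, one feature window per
#' candidate (tiled for segments wider than the window), classifier scores,
#' and the per-file flag as the OR of per-candidate decisions.
#'
#' @param rec an \code{\link{audioRecording}}.
#' @param model a trained \code{\link{ClassifierModel-class}}.
#' @param cal a \code{\link{calibrationSpec}}.
#' @param config a \code{\link{scanConfig}}.
#' @return A \code{\link{FileResult-class}}; its \code{detections} slot has
#'   one row per candidate segment with the segment's peak time, maximum
#'   window score and decision.
#' @export
scanFile <- function(rec, model, cal = calibrationSpec(),
                     config = scanConfig()) {
  stopifnot(is(rec, "AudioRecording"), is(model, "ClassifierModel"),
            inherits(config, "ScanConfig"))
  if (config$clean) rec <- removeSnaps(rec, config$cleaning)
  series <- splSeries(rec, cal, config$energy)
  segs <- candidateSegments(series, config$margin, config$minDuration,
                            config$mergeGap)

  dt <- config$features@deltaT
  dur <- duration(rec)
  det <- lapply(seq_len(nrow(segs)), function(i) {
    centers <- segs$peakTime[i]
    if (segs$end[i] - segs$start[i] > dt) {
      centers <- unique(c(centers,
        seq(segs$start[i] + dt / 2, segs$end[i] - dt / 2, by = dt / 2)))
    }
    # keep windows inside the file: a zero-padded edge window is not a
    # pattern the classifier was trained on
    centers <- if (dur >= dt) pmin(pmax(centers, dt / 2), dur - dt / 2)
               else rep(dur / 2, length(centers))
    centers <- unique(centers)
    scores <- vapply(centers, function(ct)
      predictScore(model, extractFeature(rec, ct, config$features)),
      numeric(1))
    data.frame(source = rec@sourceId, eventTime = segs$peakTime[i],
               score = max(scores), decision = max(scores) >= config$threshold,
               segStart = segs$start[i], segEnd = segs$end[i],
               peakExcess = segs$peakExcess[i], stringsAsFactors = FALSE)
  })
  det <- if (length(det)) do.call(rbind, det) else
    data.frame(source = character(), eventTime = numeric(), score = numeric(),
               decision = logical(), segStart = numeric(), segEnd = numeric(),
               peakExcess = numeric(), stringsAsFactors = FALSE)
  new("FileResult", sourceId = rec@sourceId,
      vesselPresent = nrow(det) > 0 && any(det$decision),
      detections = det, splMedian = series@splMedian)
}

#' Scan a batch of WAV files
#'
#' Applies \code{\link{scanFile}} to each path.  Per-file failures are
#' caught, reported in the \code{error} column and do not abort the batch;
#' output row order follows the input order.
#'
#' @param paths character vector of WAV paths.
#' @inheritParams scanFile
#' @return list with \code{files} (one row per input: source,
#'   vesselPresent, nDetections, splMedian, error) and \code{events}
#'   (concatenated per-candidate detection rows).
#' @export
scanBatch <- function(paths, model, cal = calibrationSpec(),
                      config = scanConfig()) {
  if (length(paths) == 0) stop("empty path list")
  rows <- list()
  events <- list()
  for (i in seq_along(paths)) {
    res <- tryCatch(scanFile(readWav(paths[i]), model, cal, config),
                    error = function(e) e)
    if (inherits(res, "error")) {
      rows[[i]] <- data.frame(source = basename(paths[i]),
                              vesselPresent = NA, nDetections = NA_integer_,
                              splMedian = NA_real_,
                              error = conditionMessage(res),
                              stringsAsFactors = FALSE)
    } else {
      rows[[i]] <- data.frame(source = res@sourceId,
                              vesselPresent = res@vesselPresent,
                              nDetections = sum(res@detections$decision),
                              splMedian = res@splMedian,
                              error = NA_character_, stringsAsFactors = FALSE)
      events[[i]] <- res@detections
    }
  }
  list(files = do.call(rbind, rows),
       events = if (length(events)) do.call(rbind, events) else NULL)
}
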