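# Evaluation against manual labels, sound-exposure metrics, and
# detection-count time series.

#' Detection accuracy
#'
#' \eqn{\rho = (N - n_\epsilon)/N}: the fraction of files whose automatic
#' flag agrees with the manual label.
#'
#' @param nTotal number of evaluated files (> 0).
#' @param nError number of disagreeing files (0..nTotal).
#' @return The exact proportion.
#' @examples
#' detectionAccuracy(200, 2)  # 0.99
#' @export
detectionAccuracy <- function(nTotal, nError) {
  if (length(nTotal) != 1 || nTotal <= 0 || nTotal != round(nTotal))
    stop("nTotal must be a positive integer")
  if (nError < 0 || nError > nTotal || nError != round(nError))
    stop("nError must be an integer in [0, nTotal]")
  (nTotal - nError) / nTotal
}

#' Evaluate scan results against manual labels
#'
#' An error is marked for a file when the detector flagged a vessel the
#' labels deny, or missed a vessel the labels assert.
#'
#' @param files data.frame from \code{\link{scanBatch}$files} (columns
#'   \code{source}, \code{vesselPresent}), or a list of
#'   \code{\link{FileResult-class}} objects.
#' @param labels label table from \code{\link{loadLabels}}.
#' @return An \code{\link{EvaluationResult-class}}.
#' @export
evaluateDetections <- function(files, labels) {
  if (is.list(files) && !is.data.frame(files)) {
    files <- do.call(rbind, lapply(files, function(r)
      data.frame(source = r@sourceId, vesselPresent = r@vesselPresent,
                 stringsAsFactors = FALSE)))
  }
  stopifnot(is.data.frame(files), is.data.frame(labels))
  if (anyNA(files$vesselPresent))
    stop("cannot evaluate files with failed scans (NA vesselPresent)")
  missing <- setdiff(files$source, labels$file)
  if (length(missing))
    stop("unlabeled files: ", paste(missing, collapse = ", "))
  lab <- labels$label[match(files$source, labels$file)]
  pred <- files$vesselPresent
  fp <- sum(pred & !lab)
  fn <- sum(!pred & lab)
  n <- nrow(files)
  new("EvaluationResult", nTotal = as.integer(n),
      nError = as.integer(fp + fn), falsePositives = as.integer(fp),
      falseNegatives = as.integer(fn),
      rho = detectionAccuracy(n, fp + fn))
}

#' Sound-exposure metrics for one candidate segment
#'
#' Peak Difference is the maximum SPL in the segment minus the file median;
#' Mean Difference averages only the above-median SPL values in the segment
#' before subtracting the median (set \code{meanScope = "file"} to average
#' all above-median frames of the file instead); Area Size is the
#' trapezoidal integral over the segment of the SPL excess over the median,
#' clamped below at zero, in dB s -- the SEL proxy.
#'
#' @param series a \code{\link{FrameEnergySeries-class}}.
#' @param segment a list or one-row data.frame with \code{start} and
#'   \code{end} in seconds (e.g. a row of \code{\link{candidateSegments}}).
#' @param meanScope \code{"segment"} (default) or \code{"file"}.
#' @return An \code{\link{SELMetrics-class}}; all three metrics are 0 when
#'   no frame in the segment exceeds the median.
#' @export
selMetrics <- function(series, segment, meanScope = c("segment", "file")) {
  stopifnot(is(series, "FrameEnergySeries"))
  meanScope <- match.arg(meanScope)
  tc <- series@frameCenters
  if (segment$start > max(tc) || segment$end < min(tc))
    stop("segment outside the series time span")
  inSeg <- tc >= segment$start & tc <= segment$end
  exc <- series@spl - series@splMedian
  segExc <- exc[inSeg]
  if (!any(segExc > 0)) {
    return(new("SELMetrics", peakDifference = 0, meanDifference = 0,
               areaSize = 0, start = segment$start, end = segment$end))
  }
  meanPool <- if (meanScope == "segment") segExc else exc
  area <- if (sum(inSeg) >= 2)
    pracma::trapz(tc[inSeg], pmax(segExc, 0)) else 0
  new("SELMetrics",
      peakDifference = max(segExc),
      meanDifference = mean(meanPool[meanPool > 0]),
      areaSize = area, start = segment$start, end = segment$end)
}

#' Linear-energy SEL area
#'
#' Alternative to the dB-scale Area Size: integrates the linear band power
#' in excess of the median power, \eqn{\int \max(10^{SPL/10} -
#' 10^{median/10}, 0)\,dt}, returned as 10 log10 of that integral (dB re
#' 1 uPa^2 s).  The dB-scale area equals the SEL only heuristically; this
#' variant is the physically additive energy.
#'
#' @inheritParams selMetrics
#' @return linear-excess SEL in dB re 1 uPa^2 s (-Inf when no excess).
#' @export
selAreaLinear <- function(series, segment) {
  stopifnot(is(series, "FrameEnergySeries"))
  tc <- series@frameCenters
  inSeg <- tc >= segment$start & tc <= segment$end
  if (sum(inSeg) < 2) return(-Inf)
  p <- 10^(series@spl[inSeg] / 10) - 10^(series@splMedian / 10)
  a <- pracma::trapz(tc[inSeg], pmax(p, 0))
  if (a <= 0) -Inf else 10 * log10(a)
}

#' Cumulative SEL per station
#'
#' Sums per-detection Area Sizes by station to the cumulative vessel noise
#' energy proxy.
#'
#' @param areas data.frame with columns \code{station} and \code{areaSize}
#'   (one row per positive detection).
#' @return data.frame(station, selCum), one row per station; zero rows for
#'   no detections.
#' @export
cumulativeSel <- function(areas) {
  stopifnot(is.data.frame(areas))
  if (nrow(areas) == 0)
    return(data.frame(station = character(), selCum = numeric()))
  agg <- stats::aggregate(areaSize ~ station, data = areas, FUN = sum)
  names(agg) <- c("station", "selCum")
  agg[order(agg$station), , drop = FALSE]
}

#' Detection counts by date and hour of day
#'
#' Aggregates per-file results into a (date x hour) grid of positive-file
#' counts; \code{nFiles} distinguishes cells with no coverage (0 files)
#' from covered cells with zero detections.
#'
#' @param files data.frame with columns \code{vesselPresent} and
#'   \code{timestamp} (POSIXct); rows with missing timestamps are excluded
#'   with a warning.
#' @return data.frame over the full observed-date x 0..23-hour grid with
#'   columns \code{date}, \code{hour}, \code{nFiles}, \code{nDetections}.
#' @export
detectionTimeseries <- function(files) {
  stopifnot(is.data.frame(files),
            all(c("vesselPresent", "timestamp") %in% names(files)))
  bad <- is.na(files$timestamp)
  if (any(bad)) {
    warning(sum(bad), " file(s) without timestamps excluded")
    files <- files[!bad, , drop = FALSE]
  }
  dates <- as.Date(files$timestamp)
  hours <- as.integer(format(files$timestamp, "%H"))
  grid <- expand.grid(date = sort(unique(dates)), hour = 0:23)
  key <- paste(dates, hours)
  gkey <- paste(grid$date, grid$hour)
  grid$nFiles <- as.integer(table(factor(key, levels = gkey)))
  pos <- key[files$vesselPresent]
  grid$nDetections <- as.integer(table(factor(pos, levels = gkey)))
  grid[order(grid$date, grid$hour), , drop = FALSE]
}

#' Parse timestamps from DSG-style filenames
#'
#' @param x filenames containing a date-time token.
#' @param pattern regex whose first capture group is the token (default
#'   \code{YYYYMMDD_HHMMSS}).
#' @param format \code{strptime} format for the captured token.
#' @param tz time zone.
#' @return POSIXct vector (NA where the pattern does not match).
#' @export
timestampFromFilename <- function(x, pattern = "(\\d{8}_\\d{6})",
                                  format = "%Y%m%d_%H%M%S", tz = "UTC") {
  m <- regmatches(x, regexpr(pattern, x))
  out <- rep(NA_character_, length(x))
  out[grepl(pattern, x)] <- m
  as.POSIXct(out, format = format, tz = tz)
}
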