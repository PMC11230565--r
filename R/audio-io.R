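# RIFF/WAVE PCM input and output and manual-label tables.
#
# Readers accept 16/24/32-bit integer PCM and 32-bit IEEE float, mono or
# multi-channel (channel 1 is taken with a warning: the target recorders are
# single-hydrophone).  Amplitudes are kept ADC-normalized in [-1, 1]; all
# conversion to pressure lives in the energy module.

#' Read a PCM WAV file
#'
#' @param path path to a RIFF/WAVE file (16/24/32-bit PCM or 32-bit float).
#' @return An \code{\link{audioRecording}} with amplitudes scaled to
#'   \[-1, 1\] (integer samples are divided by 2^(bits-1)), the header
#'   sample rate, and \code{sourceId} set to the file basename.
#' @examples
#' f <- tempfile(fileext = ".wav")
#' writeWav(audioRecording(sin(2 * pi * 440 * (0:7999) / 8000), 8000), f)
#' rec <- readWav(f)
#' sampleRate(rec)
#' @export
readWav <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))

  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL
  data <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw <- readBin(con, "raw", size)
      fmt <- list(
        audioFormat = readBin(raw[1:2], "integer", 1, 2, signed = FALSE,
                              endian = "little"),
        numChannels = readBin(raw[3:4], "integer", 1, 2, signed = FALSE,
                              endian = "little"),
        sampleRate = readBin(raw[5:8], "integer", 1, 4, endian = "little"),
        bitsPerSample = readBin(raw[15:16], "integer", 1, 2, signed = FALSE,
                                endian = "little"))
      if (size %% 2 == 1) readBin(con, "raw", 1)
    } else if (identical(id, "data")) {
      data <- readBin(con, "raw", size)
      break
    } else {
      readBin(con, "raw", size + size %% 2)
    }
  }
  if (is.null(fmt)) stop("corrupt WAV header (no fmt chunk): ", path)
  if (is.null(data) || length(data) == 0)
    stop("zero-length or missing data chunk: ", path)
  if (!fmt$audioFormat %in% c(1L, 3L))
    stop("unsupported WAV format code ", fmt$audioFormat, " (PCM/float only)")

  bits <- fmt$bitsPerSample
  x <- switch(as.character(bits),
    "16" = readBin(data, "integer", length(data) / 2, 2, signed = TRUE,
                   endian = "little") / 32768,
    "24" = {
      n <- length(data) / 3
      b <- matrix(as.integer(data), nrow = 3)
      v <- b[1, ] + b[2, ] * 256L + b[3, ] * 65536L
      v <- ifelse(v >= 8388608, v - 16777216, v)
      v / 8388608
    },
    "32" = if (fmt$audioFormat == 3L)
      readBin(data, "double", length(data) / 4, 4, endian = "little")
    else
      readBin(data, "integer", length(data) / 4, 4, endian = "little") /
        2147483648,
    stop("unsupported bit depth: ", bits))

  if (fmt$numChannels > 1L) {
    warning("multi-channel WAV (", fmt$numChannels,
            " channels); taking channel 1")
    x <- x[seq(1, length(x), by = fmt$numChannels)]
  }
  if (length(x) == 0) stop("zero-length audio: ", path)
  audioRecording(x, fmt$sampleRate, sourceId = basename(path))
}

#' Write an AudioRecording as PCM WAV
#'
#' Amplitudes outside \[-1, 1\] are clipped with a warning.  Integer samples
#' are \code{round(x * 2^(bits-1))} clamped to the representable range, so a
#' written value of 0.5 at 16 bits round-trips exactly.
#'
#' @param rec an \code{\link{audioRecording}}.
#' @param path output path.
#' @param bitDepth 16 (default), 24 or 32.
#' @return \code{path}, invisibly.
#' @export
writeWav <- function(rec, path, bitDepth = 16) {
  stopifnot(is(rec, "AudioRecording"), bitDepth %in% c(16, 24, 32))
  x <- rec@samples
  if (any(x < -1 | x > 1)) {
    warning("amplitudes outside [-1, 1] clipped on write")
    x <- pmin(1, pmax(-1, x))
  }
  full <- 2^(bitDepth - 1)
  v <- pmin(full - 1, pmax(-full, round(x * full)))
  bytes <- bitDepth / 8
  n <- length(v)
  sr <- as.integer(round(rec@sampleRate))

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + n * bytes), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(1L, con, 2, endian = "little")            # PCM
  writeBin(1L, con, 2, endian = "little")            # mono
  writeBin(sr, con, 4, endian = "little")
  writeBin(as.integer(sr * bytes), con, 4, endian = "little")
  writeBin(as.integer(bytes), con, 2, endian = "little")
  writeBin(as.integer(bitDepth), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(n * bytes), con, 4, endian = "little")
  if (bitDepth == 16) {
    writeBin(as.integer(v), con, 2, endian = "little")
  } else if (bitDepth == 24) {
    u <- ifelse(v < 0, v + 16777216, v)
    raw <- as.raw(rbind(u %% 256, (u %/% 256) %% 256, (u %/% 65536) %% 256))
    writeBin(raw, con)
  } else {
    writeBin(as.integer(v), con, 4, endian = "little")
  }
  invisible(path)
}

#' Load a manual-label table
#'
#' Reads a CSV with columns \code{file,label} mapping each recording to a
#' boolean burst-broadband vessel presence from manual review.
#'
#' @param path CSV path.
#' @return data.frame with character \code{file} and logical \code{label};
#'   duplicate filenames and unknown label strings are errors; an empty file
#'   yields an empty table with a warning.
#' @export
loadLabels <- function(path) {
  if (!file.exists(path)) stop("label file not found: ", path)
  tab <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character"),
    error = function(e) stop("unparseable label CSV: ", conditionMessage(e)))
  if (nrow(tab) == 0) {
    warning("empty label table: ", path)
    return(data.frame(file = character(), label = logical()))
  }
  if (!all(c("file", "label") %in% names(tab)))
    stop("label CSV must have columns 'file' and 'label'")
  if (anyDuplicated(tab$file))
    stop("duplicate filenames in label table: ",
         paste(unique(tab$file[duplicated(tab$file)]), collapse = ", "))
  lab <- trimws(tolower(tab$label))
  ok1 <- lab %in% c("1", "true")
  ok0 <- lab %in% c("0", "false")
  if (!all(ok1 | ok0))
    stop("unknown label values: ",
         paste(unique(tab$label[!(ok1 | ok0)]), collapse = ", "))
  data.frame(file = tab$file, label = ok1, stringsAsFactors = FALSE)
}
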