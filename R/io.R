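#' Write multichannel audio as 32-bit float WAV
#'
#' Minimal RIFF/WAVE writer (IEEE float, interleaved channels); R has no
#' multichannel WAV package in this stack so the format is handled directly.
#'
#' @param audio `multichannel_audio` or a numeric matrix (samples x channels).
#' @param path output file.
#' @param fs sampling rate, Hz (taken from `audio` when present).
#' @return `path`, invisibly.
#' @export
write_multiwav <- function(audio, path, fs = NULL) {
  if (inherits(audio, "multichannel_audio")) {
    fs <- fs %||% audio$fs
    x <- audio$samples
  } else x <- as.matrix(audio)
  if (is.null(fs)) stop("fs required", call. = FALSE)
  nch <- ncol(x); nsamp <- nrow(x)
  data_bytes <- nsamp * nch * 4L
  con <- file(path, "wb"); on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(3L, con, size = 2, endian = "little")          # IEEE float
  writeBin(as.integer(nch), con, size = 2, endian = "little")
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * nch * 4L), con, size = 4, endian = "little")
  writeBin(as.integer(nch * 4L), con, size = 2, endian = "little")
  writeBin(32L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  writeBin(as.numeric(t(x)), con, size = 4, endian = "little")
  invisible(path)
}

#' Read a multichannel float/PCM WAV file
#'
#' @param path WAV file written by [write_multiwav()] or any PCM16/float32
#'   RIFF file.
#' @return `multichannel_audio` list with `samples` (samples x channels) and
#'   `fs`.
#' @export
read_multiwav <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  riff <- readChar(con, 4); readBin(con, integer(), 1, 4, endian = "little")
  wave <- readChar(con, 4)
  if (riff != "RIFF" || wave != "WAVE") stop("not a RIFF/WAVE file", call. = FALSE)
  fmt <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, integer(), 1, 4, endian = "little")
    if (id == "fmt ") {
      fmt <- list(code = readBin(con, integer(), 1, 2, endian = "little"),
                  nch = readBin(con, integer(), 1, 2, endian = "little"),
                  fs = readBin(con, integer(), 1, 4, endian = "little"))
      readBin(con, integer(), 1, 4, endian = "little")  # byte rate
      readBin(con, integer(), 1, 2, endian = "little")  # block align
      fmt$bits <- readBin(con, integer(), 1, 2, endian = "little")
      if (sz > 16) readBin(con, raw(), sz - 16)
    } else if (id == "data") {
      if (is.null(fmt)) stop("data chunk before fmt chunk", call. = FALSE)
      if (fmt$code == 3L && fmt$bits == 32L) {
        v <- readBin(con, numeric(), sz / 4, size = 4, endian = "little")
      } else if (fmt$code == 1L && fmt$bits == 16L) {
        v <- readBin(con, integer(), sz / 2, size = 2, signed = TRUE,
                     endian = "little") / 32768
      } else stop("unsupported WAV encoding", call. = FALSE)
      samples <- t(matrix(v, nrow = fmt$nch))
      break
    } else readBin(con, raw(), sz)
  }
  if (is.null(samples)) stop("no data chunk found", call. = FALSE)
  structure(list(samples = samples, fs = fmt$fs), class = "multichannel_audio")
}

#' Write/read the standard CSV interfaces
#'
#' Tracks: `frame, mouse_id, nose_x_cm, nose_y_cm, centroid_x_cm,
#' centroid_y_cm`. Events: `time_s, vocalizer_id, source_x_cm, source_y_cm`
#' (ground truth) or the attributed-events layout produced by
#' [attribute_events()].
#'
#' @param x data.frame.
#' @param path file path.
#' @return `path` (writers) or a data.frame (readers).
#' @export
write_tracks_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks_csv
#' @export
read_tracks_csv <- function(path) utils::read.csv(path)
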