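# Minimal mono RIFF/WAVE reader and writer (16-bit PCM, plus float-32
# read). Handwritten because no WAV-capable package is among the
# dependencies; covers the single format the pipeline consumes.

#' Read a mono WAV file
#'
#' Supports 16-bit integer PCM (format 1) and 32-bit float (format 3)
#' mono files. Samples are returned in `[-1, 1]`.
#'
#' @param path Path to a `.wav` file.
#' @param group Optional group label attached to the result.
#' @return An `audio_signal`.
#' @export
read_wav <- function(path, group = NA_character_) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path, call. = FALSE)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path, call. = FALSE)
  fmt <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        audio_format = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        n_channels = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        fs = readBin(con, "integer", 1, 4, endian = "little")
      )
      invisible(readBin(con, "integer", 1, 4, endian = "little")) # byte rate
      invisible(readBin(con, "integer", 1, 2, endian = "little")) # block align
      fmt$bits <- readBin(con, "integer", 1, 2, endian = "little", signed = FALSE)
      extra <- size - 16L
      if (extra > 0) invisible(readBin(con, "raw", extra))
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("malformed WAV: data before fmt", call. = FALSE)
      if (fmt$audio_format == 1L && fmt$bits == 16L) {
        raw_vals <- readBin(con, "integer", size %/% 2L, 2, signed = TRUE,
                            endian = "little")
        samples <- raw_vals / 32768
      } else if (fmt$audio_format == 3L && fmt$bits == 32L) {
        samples <- readBin(con, "numeric", size %/% 4L, 4, endian = "little")
      } else {
        stop("unsupported WAV encoding (format ", fmt$audio_format, ", ",
             fmt$bits, " bit)", call. = FALSE)
      }
      if (size %% 2L == 1L) invisible(readBin(con, "raw", 1L))
    } else {
      invisible(readBin(con, "raw", size + size %% 2L))
    }
    if (!is.null(fmt) && !is.null(samples)) break
  }
  if (is.null(samples)) stop("no data chunk found in ", path, call. = FALSE)
  if (fmt$n_channels != 1L) {
    samples <- samples[seq(1, length(samples), by = fmt$n_channels)]
  }
  structure(list(samples = samples, fs = fmt$fs, group = group),
            class = "audio_signal")
}

#' Write a mono 16-bit PCM WAV file
#'
#' @param signal An `audio_signal` or numeric vector in `[-1, 1]` (values
#'   outside are clipped).
#' @param path Output path.
#' @param fs Sampling rate for bare vectors.
#' @return `path`, invisibly.
#' @export
write_wav <- function(signal, path, fs = NULL) {
  if (inherits(signal, "audio_signal")) {
    x <- signal$samples
    fs <- signal$fs
  } else {
    if (is.null(fs)) stop("fs required for a bare numeric signal", call. = FALSE)
    x <- as.numeric(signal)
  }
  pcm <- as.integer(pmin(32767, pmax(-32768, round(x * 32768))))
  n_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")          # PCM
  writeBin(1L, con, size = 2, endian = "little")          # mono
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(n_bytes), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
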