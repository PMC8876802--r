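## Minimal RIFF/WAVE PCM reader and writer. Only the subset the corpus uses
## is supported: uncompressed 16-bit mono PCM. Kept dependency-free on
## purpose; the format is a fixed 44-byte header plus little-endian samples.

#' Write a waveform to a 16-bit mono PCM WAV file
#'
#' Samples are clipped to `[-1, 1]` and quantized to signed 16-bit integers.
#'
#' @param waveform numeric vector of samples in `[-1, 1]`.
#' @param path output file path.
#' @param rate sampling rate in Hz.
#' @return `path`, invisibly.
#' @export
write_wav <- function(waveform, path, rate = 16000L) {
  if (!is.numeric(waveform) || length(waveform) < 1) {
    stop_invalid("'waveform' must be a non-empty numeric vector")
  }
  pcm <- as.integer(round(pmax(pmin(waveform, 1), -1) * 32767))
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop("cannot open for writing: ", path, call. = FALSE))
  on.exit(close(con), add = TRUE)
  n_bytes <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")          # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")           # PCM
  writeBin(1L, con, size = 2, endian = "little")           # mono
  writeBin(as.integer(rate), con, size = 4, endian = "little")
  writeBin(as.integer(rate) * 2L, con, size = 4, endian = "little")  # byte rate
  writeBin(2L, con, size = 2, endian = "little")           # block align
  writeBin(16L, con, size = 2, endian = "little")          # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit mono PCM WAV file
#'
#' @param path WAV file path.
#' @return list with `waveform` (numeric in `[-1, 1]`) and `rate` (Hz).
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  if (!identical(readChar(con, 4), "RIFF")) stop("not a RIFF file: ", path, call. = FALSE)
  readBin(con, "integer", 1, size = 4, endian = "little")
  if (!identical(readChar(con, 4), "WAVE")) stop("not a WAVE file: ", path, call. = FALSE)
  rate <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk in ", path, call. = FALSE)
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      if (fmt[1] != 1L || fmt[2] != 1L) {
        stop("only uncompressed mono PCM is supported: ", path, call. = FALSE)
      }
      rate <- readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 4, endian = "little")
      bits <- readBin(con, "integer", 2, size = 2, endian = "little")[2]
      if (bits != 16L) stop("only 16-bit PCM is supported: ", path, call. = FALSE)
      seek(con, size - 16L, origin = "current")
    } else if (identical(id, "data")) {
      pcm <- readBin(con, "integer", size / 2L, size = 2, endian = "little", signed = TRUE)
      return(list(waveform = pcm / 32767, rate = rate))
    } else {
      seek(con, size, origin = "current")
    }
  }
}
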