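#' Write a mono waveform to a RIFF WAV file (16-bit PCM)
#'
#' Samples are clipped to \[-1, 1\] and quantized to signed 16-bit integers.
#'
#' @param samples numeric vector of amplitudes in \[-1, 1\].
#' @param fs sampling frequency in Hz.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, fs, path) {
  stopifnot(is.numeric(samples), length(samples) > 0, fs > 0)
  pcm <- as.integer(round(pmax(-1, pmin(1, samples)) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  n_bytes <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")            # PCM
  writeBin(1L, con, size = 2, endian = "little")            # mono
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs) * 2L, con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")            # block align
  writeBin(16L, con, size = 2, endian = "little")           # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a mono RIFF WAV file (16-bit PCM)
#'
#' @param path input file path.
#' @return list with `samples` (integer amplitudes as stored) and `fs`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAV file: ", path)
  readBin(con, "integer", size = 4, endian = "little")
  wave <- readChar(con, 4)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  fs <- NULL; n_channels <- NULL; bits <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", n = 2, size = 2, endian = "little")
      if (fmt[1] != 1L) stop("only PCM WAV supported: ", path)
      n_channels <- fmt[2]
      fs <- readBin(con, "integer", size = 4, endian = "little")
      readBin(con, "integer", size = 4, endian = "little")
      readBin(con, "integer", size = 2, endian = "little")
      bits <- readBin(con, "integer", size = 2, endian = "little")
      if (sz > 16) readBin(con, "raw", n = sz - 16)
    } else if (identical(id, "data")) {
      if (is.null(bits)) stop("malformed WAV (data before fmt): ", path)
      if (bits != 16L) stop("only 16-bit PCM supported: ", path)
      samples <- readBin(con, "integer", n = sz / 2, size = 2,
                         signed = TRUE, endian = "little")
      break
    } else {
      readBin(con, "raw", n = sz + (sz %% 2))
    }
  }
  if (is.null(samples)) stop("no data chunk in WAV: ", path)
  if (n_channels != 1L)
    stop("multi-channel WAV not supported (", n_channels, " channels): ", path)
  list(samples = samples, fs = fs)
}
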