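# Minimal RIFF/WAVE I/O for mono 16-bit PCM. No audio package is part of the
# supported dependency set, so the two functions below implement exactly the
# subset of the format the pipeline uses (PCM, one channel, 16 kHz).

#' Write a waveform to a 16-bit PCM mono WAV file
#'
#' Samples are expected in `[-1, 1]`; values outside are clipped. Quantization
#' is round-to-nearest over the signed 16-bit range, so a write/read round trip
#' changes samples by at most one least-significant bit (`1/32767`).
#'
#' @param samples numeric vector of samples in `[-1, 1]`.
#' @param path output file path.
#' @param sampling_rate sampling rate in Hz (default 16000).
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, path, sampling_rate = 16000L) {
  stopifnot(is.numeric(samples), length(samples) > 0)
  pcm <- as.integer(round(pmax(pmin(samples, 1), -1) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")            # PCM
  writeBin(1L, con, size = 2, endian = "little")            # mono
  writeBin(as.integer(sampling_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sampling_rate * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")            # block align
  writeBin(16L, con, size = 2, endian = "little")           # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM mono WAV file
#'
#' @param path WAV file path.
#' @return list with `samples` (numeric in `[-1, 1]`) and `sampling_rate`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, "integer", 1, size = 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  sampling_rate <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk found in ", path)
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      if (fmt[1] != 1L) stop("only PCM WAV supported")
      if (fmt[2] != 1L) stop("only mono WAV supported")
      sampling_rate <- readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 4, endian = "little")
      ba_bits <- readBin(con, "integer", 2, size = 2, endian = "little")
      if (ba_bits[2] != 16L) stop("only 16-bit WAV supported")
      if (sz > 16) readBin(con, "raw", sz - 16L)
    } else if (identical(id, "data")) {
      pcm <- readBin(con, "integer", sz / 2L, size = 2, signed = TRUE,
                     endian = "little")
      return(list(samples = pcm / 32767, sampling_rate = sampling_rate))
    } else {
      readBin(con, "raw", sz + sz %% 2L)
    }
  }
}
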