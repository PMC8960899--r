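# Minimal RIFF/WAVE PCM16 mono I/O. No audio package is available in the
# runtime environment, and the external interface of the song generator is
# plain WAV, so the format is read and written directly.

#' Write a mono waveform to a 16-bit PCM WAV file
#'
#' @param wave numeric vector in `[-1, 1]` (values are clipped).
#' @param path output file path.
#' @param sr sample rate in Hz.
#' @return `path`, invisibly.
#' @export
write_wav <- function(wave, path, sr = DS_SR) {
  ds_assert(is.numeric(wave) && length(wave) > 0, "empty waveform")
  pcm <- as.integer(round(pmax(-1, pmin(1, wave)) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  n_bytes <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")              # PCM
  writeBin(1L, con, size = 2, endian = "little")              # mono
  writeBin(as.integer(sr), con, size = 4, endian = "little")
  writeBin(as.integer(sr * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")              # block align
  writeBin(16L, con, size = 2, endian = "little")             # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM mono WAV file
#'
#' @param path WAV file path.
#' @return list with `wave` (numeric in `[-1, 1]`) and `sr`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ds_assert(identical(readChar(con, 4), "RIFF"), "not a RIFF file")
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  ds_assert(identical(readChar(con, 4), "WAVE"), "not a WAVE file")
  sr <- NA_integer_
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk found", call. = FALSE)
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      ds_assert(fmt[1] == 1L && fmt[2] == 1L, "only PCM mono supported")
      sr <- readBin(con, "integer", 1, size = 4, endian = "little")
      invisible(readBin(con, "raw", sz - 8L))
    } else if (id == "data") {
      pcm <- readBin(con, "integer", sz / 2L, size = 2, signed = TRUE, endian = "little")
      return(list(wave = pcm / 32767, sr = sr))
    } else {
      invisible(readBin(con, "raw", sz))
    }
  }
}
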