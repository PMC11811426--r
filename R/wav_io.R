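# Minimal RIFF/WAVE PCM 16-bit mono reader/writer. Quantisation is
# deterministic, so identical waveforms give byte-identical files.

#' Write a mono waveform to a 16-bit PCM WAV file
#'
#' @param samples Numeric vector in `[-1, 1]` (values are clamped).
#' @param path Output file path.
#' @param sample_rate Sampling rate in Hz.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, path, sample_rate) {
  stopifnot(is.numeric(samples), length(samples) > 0, sample_rate > 0)
  pcm <- as.integer(round(pmin(pmax(samples, -1), 1) * 32767))
  n_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")                 # PCM
  writeBin(1L, con, size = 2, endian = "little")                 # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")                 # block align
  writeBin(16L, con, size = 2, endian = "little")                # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(n_bytes), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM mono WAV file
#'
#' @param path File path.
#' @return list with `samples` (numeric in `[-1, 1]`) and `sample_rate`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  readBin(con, "integer", 1, size = 4, endian = "little")
  wave <- readChar(con, 4)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE")) {
    stop("not a RIFF/WAVE file: ", path)
  }
  sample_rate <- NULL
  bits <- NULL
  channels <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk found in ", path)
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      channels <- fmt[2]
      sample_rate <- readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 2, endian = "little")
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (size > 16) readBin(con, "raw", size - 16L)
    } else if (identical(id, "data")) {
      if (is.null(sample_rate)) stop("data chunk before fmt chunk in ", path)
      if (bits != 16L || channels != 1L) {
        stop("only 16-bit mono PCM supported (got ", bits, "-bit, ",
             channels, " channel(s))")
      }
      pcm <- readBin(con, "integer", size / 2L, size = 2, endian = "little",
                     signed = TRUE)
      return(list(samples = pcm / 32767, sample_rate = sample_rate))
    } else {
      readBin(con, "raw", size)
    }
  }
}
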