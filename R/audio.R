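#' Mono audio sequence
#'
#' Lightweight container for a mono waveform: samples in `[-1, 1]`, a sampling
#' rate, and free-form provenance metadata (species, vocal class, subject,
#' body weight, generator ground truth, ...).
#'
#' @param samples numeric vector.
#' @param sample_rate sampling rate (Hz).
#' @param meta named list of metadata.
#' @return an object of class `audio_seq`.
#' @export
audio_seq <- function(samples, sample_rate, meta = list()) {
  if (!is.numeric(samples) || length(samples) == 0)
    abort_canicoh("audio samples must be a non-empty numeric vector",
                  "canicoh_invalid_input")
  stopifnot_scalar_num(sample_rate, "sample_rate", positive = TRUE)
  structure(list(samples = as.numeric(samples),
                 sample_rate = sample_rate, meta = meta),
            class = "audio_seq")
}

#' @export
print.audio_seq <- function(x, ...) {
  cat(sprintf("<audio_seq> %.3f s @ %g Hz (%d samples)\n",
              length(x$samples) / x$sample_rate, x$sample_rate,
              length(x$samples)))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), collapse = ", "), "\n")
  invisible(x)
}

#' @export
duration.audio_seq <- function(x, ...) length(x$samples) / x$sample_rate

#' Duration in seconds
#' @param x an object with a duration.
#' @param ... unused.
#' @export
duration <- function(x, ...) UseMethod("duration")

#' Write a mono 16-bit PCM WAV file
#'
#' @param audio an [audio_seq]. Samples are clipped to `[-1, 1]`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(audio, path) {
  x <- pmax(pmin(audio$samples, 1), -1)
  pcm <- as.integer(round(x * 32767))
  sr <- as.integer(round(audio$sample_rate))
  n <- length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * n), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")   # PCM
  writeBin(1L, con, size = 2, endian = "little")   # mono
  writeBin(sr, con, size = 4, endian = "little")
  writeBin(sr * 2L, con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * n), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a mono 16-bit PCM WAV file
#'
#' Minimal chunked reader for the files [write_wav()] produces (and any
#' canonical mono PCM16 WAV).
#' @param path file path.
#' @return an [audio_seq].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  readBin(con, integer(), size = 4, endian = "little")
  wave <- readChar(con, 4)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE"))
    abort_canicoh("not a RIFF/WAVE file", "canicoh_invalid_input")
  sr <- NULL; bits <- NULL; nchan <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, integer(), size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      nchan <- fmt[2]
      sr <- readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 2, endian = "little")
      bits <- readBin(con, integer(), size = 2, endian = "little")
      if (sz > 16) readBin(con, raw(), n = sz - 16)
    } else if (identical(id, "data")) {
      samples <- readBin(con, integer(), n = sz / 2, size = 2,
                         signed = TRUE, endian = "little")
    } else {
      readBin(con, raw(), n = sz)
    }
    if (!is.null(samples) && !is.null(sr)) break
  }
  if (is.null(samples) || is.null(sr))
    abort_canicoh("malformed WAV: missing fmt or data chunk",
                  "canicoh_invalid_input")
  if (!identical(nchan, 1L) || !identical(bits, 16L))
    abort_canicoh("only mono 16-bit PCM WAV is supported",
                  "canicoh_invalid_input")
  audio_seq(samples / 32768, sr)
}

# Linear-interpolation resampling (used for envelope alignment, where the
# content is band-limited far below the target Nyquist).
resample_linear <- function(x, fs_in, fs_out) {
  n_out <- max(2L, round(length(x) * fs_out / fs_in))
  t_out <- (seq_len(n_out) - 1) / fs_out
  stats::approx(x = (seq_along(x) - 1) / fs_in, y = x, xout = t_out,
                rule = 2)$y
}

# Block-mean decimation by an integer factor (cheap anti-alias for
# envelopes whose content sits far below the decimated Nyquist).
block_decimate <- function(x, factor) {
  if (factor <= 1) return(x)
  n <- (length(x) %/% factor) * factor
  colMeans(matrix(x[seq_len(n)], nrow = factor))
}
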