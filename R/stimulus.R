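# Word-stream stimulus construction and the 3 x 3 speech-type x speech-rate
# manipulation grid, plus per-stream word/syllable rate extraction.

#' Build a command-word stream
#'
#' Each word is high-pass filtered at 100 Hz, independently peak-normalized
#' to -2 dBFS, and the words are concatenated with silences drawn uniformly
#' from `silence_ms` +/- `half_range_ms`. True word (and, when the words
#' carry them, syllable) onsets are recorded.
#'
#' @param words list of [audio_seq] sharing one sample rate.
#' @param silence_ms mean inter-word silence (ms).
#' @param half_range_ms half-range of the uniform silence jitter (ms).
#' @param seed integer RNG seed for the silences, or `NULL` to use the
#'   current RNG stream.
#' @param highpass_hz per-word high-pass cutoff (Hz).
#' @param norm_dbfs per-word peak normalization target (dBFS).
#' @return an object of class `word_stream`: `audio`, `word_onsets_s`,
#'   `word_durs_s`, `syllable_onsets_s`, `speech_type` ("normal"),
#'   `rate_factor` (1), `silence_spec`.
#' @export
build_stream <- function(words, silence_ms = 300, half_range_ms = 50,
                         seed = NULL, highpass_hz = 100, norm_dbfs = -2) {
  if (!length(words))
    abort_canicoh("need at least 1 word", "canicoh_invalid_input")
  srs <- vapply(words, function(w) w$sample_rate, 0)
  if (length(unique(srs)) != 1)
    abort_canicoh("words must share one sample rate", "canicoh_invalid_input")
  sr <- srs[1]
  target_peak <- 10^(norm_dbfs / 20)
  proc <- lapply(words, function(w) {
    x <- butter_filtfilt(w$samples, sr, highpass_hz, "high", 4L)
    x * target_peak / max(abs(x))
  })
  gaps_s <- with_seed(seed, {
    if (length(words) > 1)
      stats::runif(length(words) - 1,
                   (silence_ms - half_range_ms) / 1000,
                   (silence_ms + half_range_ms) / 1000)
    else numeric(0)
  })
  onsets <- numeric(length(words))
  durs <- vapply(proc, length, 0L) / sr
  pieces <- list()
  t <- 0
  syl <- numeric(0)
  for (i in seq_along(proc)) {
    onsets[i] <- t
    pieces[[length(pieces) + 1]] <- proc[[i]]
    so <- words[[i]]$meta$syllable_onsets_s
    if (!is.null(so)) syl <- c(syl, t + so)
    t <- t + durs[i]
    if (i < length(proc)) {
      pieces[[length(pieces) + 1]] <- numeric(round(gaps_s[i] * sr))
      t <- t + round(gaps_s[i] * sr) / sr
    }
  }
  # carry per-word F0 contours (a pitch tier) when the words know them;
  # the prosody manipulations then warp against the exact intended contour
  contours <- lapply(words, function(w) w$meta$f0_contour)
  if (any(vapply(contours, is.null, TRUE))) contours <- NULL
  structure(list(audio = audio_seq(unlist(pieces), sr),
                 word_onsets_s = onsets, word_durs_s = durs,
                 syllable_onsets_s = if (length(syl)) syl else NULL,
                 speech_type = "normal", rate_factor = 1L,
                 silence_spec = c(mean_ms = silence_ms,
                                  half_range_ms = half_range_ms),
                 meta = list(f0_contours = contours)),
            class = "word_stream")
}

#' @export
print.word_stream <- function(x, ...) {
  cat(sprintf(
    "<word_stream> %d words, %.3f s, speech_type=%s, rate_factor=%d\n",
    length(x$word_onsets_s), duration(x$audio), x$speech_type,
    x$rate_factor))
  invisible(x)
}

# iterate over word segments of a stream, applying `fun(samples)` in place
map_words <- function(stream, fun) {
  sr <- stream$audio$sample_rate
  x <- stream$audio$samples
  for (i in seq_along(stream$word_onsets_s)) {
    i0 <- round(stream$word_onsets_s[i] * sr) + 1L
    i1 <- min(i0 + round(stream$word_durs_s[i] * sr) - 1L, length(x))
    x[i0:i1] <- fun(x[i0:i1], i)
  }
  stream$audio$samples <- x
  stream
}

word_f0_contours <- function(stream) {
  sr <- stream$audio$sample_rate
  lapply(seq_along(stream$word_onsets_s), function(i) {
    i0 <- round(stream$word_onsets_s[i] * sr) + 1L
    i1 <- min(i0 + round(stream$word_durs_s[i] * sr) - 1L,
              length(stream$audio$samples))
    seg <- stream$audio$samples[i0:i1]
    pt <- tryCatch(pitch_track(audio_seq(seg, sr)),
                   canicoh_unvoiced_input = function(e) NULL,
                   canicoh_invalid_input = function(e) NULL)
    if (is.null(pt)) NULL else f0_curve(pt$frames, length(seg), sr)
  })
}

#' Apply a speech-type manipulation to a word stream
#'
#' Three modes mirror the stimulus constructions:
#' * `content_only` - prosody removed: the F0 contour of every word is
#'   flattened to `reference_f0_hz` and the intensity contour is
#'   time-reversed within each word (speech stays forward).
#' * `prosody_only` - content removed: every word is time-reversed in
#'   place, then the original per-word F0 and intensity contours are
#'   re-imposed, reinstating the original prosody.
#' * `normal` - control round trip: F0 flattened then the original contour
#'   re-imposed, so processing artefacts match the other conditions.
#'
#' Total duration is preserved to within one frame in all modes.
#'
#' @param stream a [build_stream()] result carrying normal input material.
#' @param mode one of "normal", "content_only", "prosody_only".
#' @param reference_f0_hz flattening target (Hz); default the median voiced
#'   F0 of the stream.
#' @return the manipulated `word_stream` (speech_type updated).
#' @export
apply_speech_type <- function(stream,
                              mode = c("normal", "content_only",
                                       "prosody_only"),
                              reference_f0_hz = NULL) {
  if (!inherits(stream, "word_stream"))
    abort_canicoh("`stream` must be a word_stream", "canicoh_invalid_input")
  if (!is.character(mode) ||
      !mode[1] %in% c("normal", "content_only", "prosody_only"))
    abort_canicoh("unknown speech-type mode", "canicoh_invalid_argument")
  mode <- mode[1]
  sr <- stream$audio$sample_rate
  # use the stream's own pitch tier when it has one (exact contours make
  # the reversal remap a true involution); fall back to tracking
  contours <- stream$meta$f0_contours
  if (is.null(contours)) contours <- word_f0_contours(stream)
  if (is.null(reference_f0_hz)) {
    all_f0 <- unlist(contours)
    reference_f0_hz <- if (length(all_f0)) stats::median(all_f0) else 150
  }
  fit_len <- function(cv, n) {
    if (is.null(cv)) return(NULL)
    if (length(cv) == n) cv
    else stats::approx(seq_along(cv), cv, xout = seq(1, length(cv),
                                                     length.out = n))$y
  }
  out_contours <- contours
  out <- map_words(stream, function(seg, i) {
    src <- fit_len(contours[[i]], length(seg))
    if (is.null(src)) return(seg)  # unvoiced word: leave untouched
    out_contours[[i]] <<-
      if (mode == "content_only") rep(reference_f0_hz, length(seg)) else src
    if (mode == "content_only") {
      flat <- pitch_remap(seg, sr, target_f0 = reference_f0_hz,
                       source_f0 = src)
      env <- moving_rms(flat, sr)
      flat * intensity_gain(env, rev(env))
    } else if (mode == "prosody_only") {
      env0 <- moving_rms(seg, sr)
      # flatten intensity first (bounded division by the word's own
      # envelope), then reverse the carrier, then re-impose the original
      # intensity contour: no gain blow-ups at attacks or silences
      carrier <- seg / pmax(env0, 0.01 * max(env0))
      rev_carrier <- rev(carrier)
      # the reversal also reversed the pitch contour; map it back
      fixed <- pitch_remap(rev_carrier, sr, target_f0 = src,
                        source_f0 = rev(src))
      fixed * env0
    } else {
      env0 <- moving_rms(seg, sr)
      flat <- pitch_remap(seg, sr, target_f0 = reference_f0_hz,
                       source_f0 = src)
      back <- pitch_remap(flat, sr, target_f0 = src,
                       source_f0 = rep(reference_f0_hz, length(seg)))
      back * intensity_gain(moving_rms(back, sr), env0)
    }
  })
  out$speech_type <- mode
  out$meta$f0_contours <- out_contours
  out
}

#' Pitch-preserving tempo change
#'
#' Phase-vocoder time-scale modification: the stream (words and silences)
#' is compressed by `factor` without shifting the pitch. Onset annotations
#' are rescaled by 1/factor.
#'
#' @param stream a `word_stream`.
#' @param factor compression factor, one of 1, 2, 4 by default.
#' @param allowed_factors widen the accepted set if needed.
#' @return the compressed `word_stream` (`rate_factor` updated).
#' @export
change_tempo <- function(stream, factor, allowed_factors = c(1, 2, 4)) {
  if (!inherits(stream, "word_stream"))
    abort_canicoh("`stream` must be a word_stream", "canicoh_invalid_input")
  if (!is.numeric(factor) || length(factor) != 1 ||
      !factor %in% allowed_factors)
    abort_canicoh("tempo factor must be one of the allowed factors",
                  "canicoh_invalid_argument")
  if (factor == 1) return(stream)
  sr <- stream$audio$sample_rate
  y <- pv_time_compress(stream$audio$samples, factor)
  stream$audio <- audio_seq(y, sr, meta = stream$audio$meta)
  stream$word_onsets_s <- stream$word_onsets_s / factor
  stream$word_durs_s <- stream$word_durs_s / factor
  if (!is.null(stream$syllable_onsets_s))
    stream$syllable_onsets_s <- stream$syllable_onsets_s / factor
  # pitch tier: pitch values unchanged, time axis compressed
  if (!is.null(stream$meta$f0_contours))
    stream$meta$f0_contours <- lapply(stream$meta$f0_contours, function(cv) {
      if (is.null(cv)) return(NULL)
      cv[round(seq(1, length(cv), length.out = round(length(cv) / factor)))]
    })
  stream$rate_factor <- as.integer(factor)
  stream
}

# Phase vocoder: compress duration by `factor` (>1), preserving pitch.
# Hann analysis/synthesis windows, synthesis hop N/4, phase propagation by
# instantaneous frequency.
pv_time_compress <- function(x, factor, N = 1024L) {
  n <- length(x)
  N <- min(N, 2^floor(log2(max(n / 4, 64))))
  hop_s <- N %/% 4L
  hop_a <- hop_s * factor
  win <- 0.5 - 0.5 * cos(2 * pi * (seq_len(N) - 1) / N)
  n_frames <- max(2L, floor((n - N) / hop_a) + 1L)
  out_len <- round(n / factor)
  y <- numeric(out_len + N)
  wsum <- numeric(out_len + N)
  omega <- 2 * pi * (seq_len(N) - 1) / N
  phi_syn <- NULL
  prev_phase <- NULL
  for (j in seq_len(n_frames)) {
    a0 <- round((j - 1) * hop_a) + 1L
    fr <- x[a0:(a0 + N - 1L)]
    S <- stats::fft(fr * win)
    mag <- Mod(S); phase <- Arg(S)
    if (is.null(phi_syn)) {
      phi_syn <- phase
    } else {
      dphi <- phase - prev_phase - omega * hop_a
      dphi <- dphi - 2 * pi * round(dphi / (2 * pi))
      inst <- omega + dphi / hop_a
      phi_syn <- phi_syn + inst * hop_s
    }
    prev_phase <- phase
    fr_syn <- Re(stats::fft(mag * exp(1i * phi_syn), inverse = TRUE)) / N
    s0 <- (j - 1L) * hop_s + 1L
    idx <- s0:(s0 + N - 1L)
    y[idx] <- y[idx] + fr_syn * win
    wsum[idx] <- wsum[idx] + win^2
  }
  y <- y / pmax(wsum, 1e-8)
  length(y) <- out_len
  y[is.na(y)] <- 0
  y
}

#' Word and syllable rates of a stream
#'
#' Computes the Hilbert envelope from the first word onset (30 Hz low-pass,
#' eighth-order Butterworth), then reads the word rate and the syllable
#' rate as the spectral peaks of the envelope power spectrum in the slow
#' and fast bands.
#'
#' @param stream a `word_stream` of at least 1 s.
#' @param word_band_hz slow band searched for the word rate (Hz).
#' @param syll_band_hz fast band searched for the syllable rate (Hz).
#' @return list(word_rate_hz, syllable_rate_hz, freq, power).
#' @export
stream_rates <- function(stream, word_band_hz = c(0.5, 3),
                         syll_band_hz = c(3, 10)) {
  if (!inherits(stream, "word_stream"))
    abort_canicoh("`stream` must be a word_stream", "canicoh_invalid_input")
  sr <- stream$audio$sample_rate
  i0 <- round(stream$word_onsets_s[1] * sr) + 1L
  x <- stream$audio$samples[i0:length(stream$audio$samples)]
  if (length(x) / sr < 1)
    abort_canicoh("stream must be at least 1 s", "canicoh_insufficient_duration")
  env <- compute_envelope(audio_seq(x, sr), band_hz = NULL,
                          env_lowpass_hz = 30, order = 8L,
                          decimate_to = 100)
  v <- env$values - mean(env$values)
  nfft <- 2^ceiling(log2(length(v) * 8))  # zero-pad for a fine peak grid
  P <- Mod(stats::fft(c(v, numeric(nfft - length(v)))))^2
  freq <- (seq_len(nfft %/% 2 + 1) - 1) * env$sample_rate / nfft
  P <- P[seq_along(freq)]
  pick <- function(band) {
    sel <- freq >= band[1] & freq <= band[2]
    if (!any(sel)) abort_canicoh("band outside spectrum",
                                 "canicoh_invalid_argument")
    freq[sel][which.max(P[sel])]
  }
  list(word_rate_hz = pick(word_band_hz),
       syllable_rate_hz = pick(syll_band_hz),
       freq = freq, power = P)
}

#' Generate the full 3 x 3 condition grid
#'
#' Crosses the three speech types with the three rate factors, yielding the
#' nine word-stream conditions, reproducibly from the input stream.
#'
#' @param stream normal-material `word_stream`.
#' @param rate_factors rate factors (default 1, 2, 4).
#' @param speech_types speech types (default all three).
#' @return named list of 9 `word_stream`s ("<type>_x<factor>").
#' @export
condition_grid <- function(stream, rate_factors = c(1, 2, 4),
                           speech_types = c("normal", "content_only",
                                            "prosody_only")) {
  out <- list()
  for (st in speech_types) {
    typed <- apply_speech_type(stream, st)
    for (rf in rate_factors) {
      out[[sprintf("%s_x%d", st, rf)]] <- change_tempo(typed, rf)
    }
  }
  out
}
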