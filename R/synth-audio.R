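# Seeded synthetic audio generators. These state a known ground truth
# (repetition rate, onset times, F0 contour) in the metadata so downstream
# estimators can be tested without any recordings.

#' Specification of a synthetic call train
#'
#' A pulse-train vocal sequence: Gaussian-windowed sinusoid bursts repeated
#' at a known mean rate, standing in for vocal sequences (barks, howls, ...)
#' whose repetition rhythm the envelope analysis estimates.
#'
#' @param rate_hz mean call repetition rate (Hz), > 0.
#' @param duration_s total duration (s); must contain at least 3 calls.
#' @param carrier_hz within-call carrier frequency (Hz).
#' @param call_dur_s single-call duration (s); must be < 1 / rate_hz.
#' @param jitter_sd_s SD of Gaussian jitter on inter-call intervals (s).
#' @param sample_rate audio sampling rate (Hz).
#' @param seed integer RNG seed.
#' @return an object of class `call_train_spec`.
#' @export
call_train_spec <- function(rate_hz, duration_s, carrier_hz = 500,
                            call_dur_s = 0.25 / rate_hz, jitter_sd_s = 0,
                            sample_rate = 16000, seed = 1L) {
  stopifnot_scalar_num(rate_hz, "rate_hz", positive = TRUE)
  stopifnot_scalar_num(duration_s, "duration_s", positive = TRUE)
  stopifnot_scalar_num(carrier_hz, "carrier_hz", positive = TRUE)
  stopifnot_scalar_num(call_dur_s, "call_dur_s", positive = TRUE)
  stopifnot_scalar_num(sample_rate, "sample_rate", positive = TRUE)
  if (call_dur_s >= 1 / rate_hz)
    abort_canicoh("calls overlap: call_dur_s must be < 1 / rate_hz",
                  "canicoh_invalid_spec")
  if (duration_s < 3 / rate_hz)
    abort_canicoh("duration_s must allow at least 3 calls (>= 3 / rate_hz)",
                  "canicoh_invalid_spec")
  if (jitter_sd_s < 0)
    abort_canicoh("jitter_sd_s must be >= 0", "canicoh_invalid_spec")
  structure(list(rate_hz = rate_hz, duration_s = duration_s,
                 carrier_hz = carrier_hz, call_dur_s = call_dur_s,
                 jitter_sd_s = jitter_sd_s, sample_rate = sample_rate,
                 seed = as.integer(seed)),
            class = "call_train_spec")
}

#' Generate a synthetic call train
#'
#' Gaussian-windowed carrier bursts at the specified mean rate. The true
#' rate and realized onsets are stored in the result's metadata.
#'
#' @param spec a [call_train_spec()].
#' @return an [audio_seq] with metadata `true_rate_hz`, `onsets_s`.
#' @export
gen_call_sequence <- function(spec) {
  if (!inherits(spec, "call_train_spec"))
    abort_canicoh("`spec` must be a call_train_spec", "canicoh_invalid_spec")
  sr <- spec$sample_rate
  n <- round(spec$duration_s * sr)
  with_seed(spec$seed, {
    n_calls <- floor(spec$duration_s * spec$rate_hz)
    onsets <- (seq_len(n_calls) - 1) / spec$rate_hz
    if (spec$jitter_sd_s > 0)
      onsets <- onsets + c(0, stats::rnorm(n_calls - 1, 0, spec$jitter_sd_s))
    onsets <- pmax(onsets, 0)
    x <- numeric(n)
    m <- round(spec$call_dur_s * sr)
    tt <- (seq_len(m) - 1) / sr
    # Gaussian window with +-3 SD support inside the call
    win <- exp(-0.5 * ((tt - spec$call_dur_s / 2) / (spec$call_dur_s / 6))^2)
    burst <- win * sin(2 * pi * spec$carrier_hz * tt)
    for (o in onsets) {
      i0 <- round(o * sr) + 1L
      idx <- i0:min(i0 + m - 1L, n)
      x[idx] <- x[idx] + burst[seq_along(idx)]
    }
    audio_seq(0.9 * x / max(abs(x)), sr,
              meta = list(true_rate_hz = spec$rate_hz, onsets_s = onsets,
                          carrier_hz = spec$carrier_hz,
                          generator = "gen_call_sequence",
                          seed = spec$seed))
  })
}

# One synthetic "word": harmonic carrier (sawtooth-like spectrum) whose F0
# follows a rise-fall contour, amplitude-modulated into syllable bumps.
make_word <- function(n_syllables, syllable_rate_hz, f0_hz, sample_rate,
                      contour_depth = 0.2) {
  sr <- sample_rate
  dur <- n_syllables / syllable_rate_hz
  n <- round(dur * sr)
  t <- (seq_len(n) - 1) / sr
  # natural-sounding prosodic contour: rise then fall, +-contour_depth
  f0_t <- f0_hz * (1 + contour_depth * sin(pi * t / dur))
  phase <- 2 * pi * cumsum(f0_t) / sr
  nh <- max(1L, floor(min(8, (sr / 2 - 1) / max(f0_t))))
  x <- numeric(n)
  for (h in seq_len(nh)) x <- x + sin(h * phase) / h
  # speech-like asymmetric syllable bumps: fast attack, slow decay
  syl_dur <- 1 / syllable_rate_hz
  phase_syl <- (t %% syl_dur) / syl_dur       # 0..1 within each syllable
  attack <- 0.15
  env <- ifelse(phase_syl < attack,
                0.5 - 0.5 * cos(pi * phase_syl / attack),
                (0.5 + 0.5 * cos(pi * (phase_syl - attack) /
                                   (1 - attack)))^1.5)
  syl_onsets <- (seq_len(n_syllables) - 1) / syllable_rate_hz
  audio_seq(x * env / max(abs(x * env)), sr,
            meta = list(f0_hz = f0_hz, f0_contour = f0_t,
                        syllable_onsets_s = syl_onsets,
                        n_syllables = n_syllables))
}

#' Generate a synthetic command-word stream
#'
#' Emulates the stimulus construction of short command-word streams: a few
#' mono-/disyllabic harmonic "words" separated by silences drawn uniformly
#' from `silence_ms` +/- `silence_jitter_ms` (half-range reading of the
#' "300 +/- 50 ms" convention). Ground-truth word and syllable onsets are
#' returned as annotations.
#'
#' @param n_words number of words (>= 1).
#' @param syllable_rate_hz within-word syllable rate (Hz).
#' @param silence_ms mean inter-word silence (ms).
#' @param silence_jitter_ms half-range of the uniform silence jitter (ms).
#' @param f0_hz base fundamental frequency of the synthetic voice (Hz).
#' @param sample_rate audio sampling rate (Hz).
#' @param seed integer RNG seed.
#' @return a `word_stream` (see [build_stream()]) whose metadata carries the
#'   true syllable rate.
#' @export
gen_word_stream <- function(n_words = 5, syllable_rate_hz = 4,
                            silence_ms = 300, silence_jitter_ms = 50,
                            f0_hz = 220, sample_rate = 16000, seed = 1L) {
  if (!is.numeric(n_words) || n_words < 1)
    abort_canicoh("n_words must be >= 1", "canicoh_invalid_spec")
  stopifnot_scalar_num(syllable_rate_hz, "syllable_rate_hz", positive = TRUE)
  stopifnot_scalar_num(f0_hz, "f0_hz", positive = TRUE)
  if (silence_ms <= 0)
    abort_canicoh("silence_ms must be > 0", "canicoh_invalid_spec")
  with_seed(seed, {
    # alternate disyllabic and monosyllabic words, as in command speech
    nsyl <- rep(c(2L, 1L), length.out = n_words)
    words <- lapply(nsyl, make_word, syllable_rate_hz = syllable_rate_hz,
                    f0_hz = f0_hz, sample_rate = sample_rate)
    stream <- build_stream(words, silence_ms = silence_ms,
                           half_range_ms = silence_jitter_ms, seed = NULL)
    stream$meta <- c(stream$meta,   # keep the pitch tier build_stream wrote
                     list(true_syllable_rate_hz = syllable_rate_hz,
                          f0_hz = f0_hz, seed = seed,
                          generator = "gen_word_stream"))
    stream
  })
}
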