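# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# word-stream envelope resampled to the EEG rate (500 Hz)
stream_env_500 <- function(seed) {
  fixture(paste0("env500_", seed), function() {
    st <- gen_word_stream(5, 4, seed = seed)
    ev <- compute_envelope(st$audio, band_hz = NULL, env_lowpass_hz = 30,
                           order = 8, decimate_to = NULL)
    canicoh:::resample_linear(ev$values, ev$sample_rate, 500)
  })
}

envelope_pool_500 <- function(n = 5)
  lapply(seq_len(n), stream_env_500)

base_stream <- function() fixture("base_stream",
                                  function() gen_word_stream(5, 4, seed = 7))

# aperiodic stimulus envelope (rectified 1/f noise, 8 Hz low-passed):
# no quasi-periodicity, so misalignment controls are meaningful
aperiodic_env_500 <- function(dur_s = 10, seed = 10) {
  fixture(paste0("apenv_", dur_s, "_", seed), function() {
    sr <- 500
    raw <- with_seed_local(seed, canicoh:::one_over_f_noise(sr * dur_s, sr, 1))
    env <- canicoh:::butter_filtfilt(abs(raw), sr, 8, "low", 4L)
    env - min(env) + 0.05
  })
}

with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv())
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  code
}

# plain sine audio helper
sine_audio <- function(freq, dur = 1, sr = 16000, amp = 1) {
  t <- seq(0, dur - 1 / sr, by = 1 / sr)
  audio_seq(amp * sin(2 * pi * freq * t), sr)
}

# textbook periodogram argmax (independent oracle for rate estimates)
fft_peak_hz <- function(values, fs, lo, hi, pad = 8) {
  v <- values - mean(values)
  nfft <- 2^ceiling(log2(length(v) * pad))
  P <- Mod(stats::fft(c(v, numeric(nfft - length(v)))))^2
  fr <- (seq_len(nfft %/% 2) - 1) * fs / nfft
  sel <- fr >= lo & fr <= hi
  fr[sel][which.max(P[sel])]
}
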