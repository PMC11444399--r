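# Envelope, rhythm, spectral features, and the PIC statistic.

test_that("compute_envelope recovers amplitude and modulators", {
  # constant-amplitude tone: envelope ~ amplitude everywhere (< 1% error)
  a <- sine_audio(440, dur = 2, amp = 0.8)
  env <- compute_envelope(a, band_hz = NULL, env_lowpass_hz = 20)
  mid <- seq(40, length(env$values) - 40)
  expect_lt(max(abs(env$values[mid] - 0.8)) / 0.8, 0.01)
  # AM tone: recovered envelope correlates > 0.99 with the modulator
  sr <- 16000
  t <- seq(0, 3 - 1 / sr, by = 1 / sr)
  mod <- 1 + 0.5 * cos(2 * pi * 2 * t)
  am <- audio_seq(0.4 * mod * sin(2 * pi * 500 * t), sr)
  env2 <- compute_envelope(am, band_hz = c(100, 5000))
  mod_dec <- canicoh:::resample_linear(mod, sr, env2$sample_rate)
  n <- min(length(mod_dec), length(env2$values))
  mid <- seq(20, n - 20)
  expect_gt(stats::cor(env2$values[mid], mod_dec[mid]), 0.99)
  expect_true(all(env2$values >= 0))
  # error cases
  expect_error(audio_seq(numeric(0), 16000),
               class = "canicoh_invalid_input")
  expect_error(compute_envelope(a, env_lowpass_hz = 9000),
               class = "canicoh_invalid_input")
})

test_that("envelope_rate finds the dominant modulation and honours the
          search range, ties, and errors", {
  # deep 2 Hz + shallow 6 Hz modulation: argmax must be 2 Hz
  fs <- 200
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  vals <- 1 + 0.8 * sin(2 * pi * 2 * t) + 0.3 * sin(2 * pi * 6 * t)
  env <- structure(list(values = pmax(vals, 0), sample_rate = fs,
                        lowpass_hz = 20, filter_order = 4),
                   class = "envelope")
  est <- envelope_rate(env, search_range_hz = c(0.5, 10))
  oracle <- fft_peak_hz(env$values, fs, 0.5, 10)
  expect_equal(oracle, 2, tolerance = 0.02)
  expect_lt(abs(est$peak_hz - oracle), 0.05 + 1e-9)
  # peak always inside the search range
  est2 <- envelope_rate(env, search_range_hz = c(4, 10))
  expect_gte(est2$peak_hz, 4)
  # flat envelope: no peak
  flat <- structure(list(values = rep(1, 2000), sample_rate = fs,
                         lowpass_hz = 20, filter_order = 4),
                    class = "envelope")
  expect_error(envelope_rate(flat), class = "canicoh_no_peak")
  # too short for the lowest search frequency
  short <- structure(list(values = vals[1:100], sample_rate = fs,
                          lowpass_hz = 20, filter_order = 4),
                     class = "envelope")
  expect_error(envelope_rate(short, search_range_hz = c(0.5, 10)),
               class = "canicoh_insufficient_duration")
})

test_that("envelope_rate is amplitude-scale invariant and commutes with
          time compression", {
  a <- gen_call_sequence(call_train_spec(2.4, 10, seed = 8))
  env <- compute_envelope(a)
  r1 <- envelope_rate(env)$peak_hz
  env_scaled <- env
  env_scaled$values <- env$values * 7.3
  expect_identical(envelope_rate(env_scaled)$peak_hz, r1)
  # compressing the waveform by k multiplies the rate by k
  k <- 2
  comp <- audio_seq(a$samples, a$sample_rate * k)
  rk <- envelope_rate(compute_envelope(comp, decimate_to = 200),
                      search_range_hz = c(0.5, 10))$peak_hz
  expect_lt(abs(rk - k * r1), k * 0.05 + 1e-9)
})

test_that("dominant_frequency picks the in-band, higher-amplitude tone", {
  expect_lt(abs(dominant_frequency(sine_audio(440)) - 440), 4)
  sr <- 16000
  t <- seq(0, 1 - 1 / sr, by = 1 / sr)
  two <- audio_seq(sin(2 * pi * 200 * t) + 0.5 * sin(2 * pi * 800 * t), sr)
  expect_lt(abs(dominant_frequency(two) - 200), 4)
  # strong out-of-band tone excluded; agrees with an in-band FFT oracle
  mix <- audio_seq(3 * sin(2 * pi * 3000 * t) + 0.2 * sin(2 * pi * 300 * t),
                   sr)
  got <- dominant_frequency(mix, band_hz = c(50, 2000))
  oracle <- fft_peak_hz(mix$samples, sr, 50, 2000, pad = 1)
  expect_lt(abs(got - 300), 4)
  expect_lt(abs(got - oracle), 4)
  expect_error(dominant_frequency(audio_seq(numeric(1600) + 0, 16000)),
               class = "canicoh_no_peak")
  expect_error(dominant_frequency(sine_audio(440, dur = 0.05)),
               class = "canicoh_invalid_input")
})

test_that("dominant_frequency property: exhaustive two-tone grid", {
  sr <- 8000
  t <- seq(0, 0.5 - 1 / sr, by = 1 / sr)
  for (f1 in c(150, 400, 900)) for (f2 in c(250, 700, 1500)) {
    if (abs(f1 - f2) < 100) next
    x <- audio_seq(sin(2 * pi * f1 * t) + 0.4 * sin(2 * pi * f2 * t), sr)
    expect_lt(abs(dominant_frequency(x, band_hz = c(50, 2000)) - f1), 8)
  }
})

test_that("pitch_track: sawtooth, glide, and unvoiced input", {
  sr <- 16000
  t <- seq(0, 1 - 1 / sr, by = 1 / sr)
  saw <- audio_seq(2 * ((150 * t) %% 1) - 1, sr)
  pt <- pitch_track(saw)
  expect_lt(abs(pt$f0_mean_hz - 150) / 150, 0.02)
  # linear glide 100 -> 200 Hz: mean ~ 150, IQR ~ 50 (+- 10%)
  f0t <- 100 + 100 * t
  ph <- 2 * pi * cumsum(f0t) / sr
  glide <- audio_seq(rowSums(sapply(1:6, function(h) sin(h * ph) / h)), sr)
  pg <- pitch_track(glide)
  expect_lt(abs(pg$f0_mean_hz - 150) / 150, 0.1)
  expect_lt(abs(pg$f0_iqr_hz - 50) / 50, 0.1)
  set.seed(2)
  expect_error(pitch_track(audio_seq(rnorm(16000), sr)),
               class = "canicoh_unvoiced_input")
})

test_that("pic_index matches hand computations and flags degeneracy", {
  # n = 2 everywhere: the small-sample corrections cancel; PIC = 2/3
  p <- pic_index(list(A = c(1, 3), B = c(2, 6)))
  expect_equal(p$pic, 2 / 3)
  # identical individuals: CVb = 0 => PIC = 0
  expect_equal(pic_index(list(A = c(1, 2), B = c(1, 2)))$pic, 0)
  # zero within-variance everywhere: undefined
  expect_error(pic_index(list(A = c(1, 1), B = c(3, 3))),
               class = "canicoh_degenerate_variance")
  expect_error(pic_index(list(A = c(1, 2))),
               class = "canicoh_invalid_input")
  expect_error(pic_index(list(A = c(-2, 1), B = c(1, 2))),
               class = "canicoh_invalid_input")
  # small-sample correction applied: CVw of c(1, 3) is sqrt(2)/2*100*9/8
  expect_equal(unname(p$cv_within_by_individual["A"]),
               sqrt(2) / 2 * 100 * (1 + 1 / 8))
})

test_that("PIC separates high and low distinctiveness regimes", {
  set.seed(42)
  picks <- replicate(20, {
    between <- lapply(1:6, function(i)
      rnorm(5, mean = 10 + 3 * i, sd = 0.3))
    within <- lapply(1:6, function(i) rnorm(5, mean = 12, sd = 3))
    c(pic_index(between)$pic, pic_index(within)$pic)
  })
  expect_true(all(picks[1, ] > 1))
  expect_true(mean(picks[2, ] < 1) >= 0.95)
})
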