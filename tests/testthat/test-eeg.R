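# Preprocessing, time-frequency power, peak-power frequency, and
# stimulus-reconstruction decoding.

make_recording <- function(n_events = 8, dur_s = 3, sr = 500, seed = 1,
                           n_chan = 2) {
  set.seed(seed)
  n <- sr * (n_events * (dur_s + 2) + 4)
  data <- matrix(rnorm(n_chan * n), n_chan, n)
  onsets <- round(seq(2 * sr, n - (dur_s + 1) * sr,
                      length.out = n_events))
  eeg_recording(data, paste0("ch", seq_len(n_chan)), sr,
                data.frame(onset_sample = onsets, condition = "normal_x1",
                           duration_s = dur_s))
}

test_that("preprocess_epochs keeps clean trials and drops the injected
          outlier found by a brute-force z oracle", {
  rec <- make_recording(seed = 5)
  ep <- preprocess_epochs(rec, "ch1", "dog")
  expect_true(all(ep$kept_mask))
  expect_equal(ep$t0_s, -1)
  # inject a 10x spike into trial 3
  rec2 <- rec
  o <- rec$events$onset_sample[3]
  rec2$data[1, o:(o + 100)] <- rec2$data[1, o:(o + 100)] + 10
  ep2 <- preprocess_epochs(rec2, "ch1", "dog")
  expect_equal(which(!ep2$kept_mask), 3L)
  # brute-force oracle on the stored z values
  z <- ep2$meta$z_max
  expect_true(z[3] > 6 && all(z[-3] <= 6))
  expect_error(preprocess_epochs(rec, "nope", "dog"),
               class = "canicoh_invalid_input")
  rec3 <- rec
  rec3$events <- rec3$events[0, ]
  expect_error(preprocess_epochs(rec3, "ch1", "dog"),
               class = "canicoh_invalid_input")
})

test_that("line-noise probes are notched >= 20 dB and preprocessing is
          idempotent", {
  sr <- 500
  rec <- make_recording(seed = 6)
  t <- (seq_len(ncol(rec$data)) - 1) / sr
  rec$data[1, ] <- rec$data[1, ] + 5 * sin(2 * pi * 50 * t) +
    sin(2 * pi * 30 * t)
  ep <- preprocess_epochs(rec, "ch1", "dog", z_cutoff = 50)
  tr <- colMeans(ep$trials)
  P <- Mod(stats::fft(tr))^2
  fr <- (seq_along(P) - 1) * sr / length(P)
  p50 <- sum(P[fr >= 49 & fr <= 51])
  p30 <- sum(P[fr >= 29 & fr <= 31])
  # 5x input ratio reversed by >= 20 dB net attenuation
  expect_lt(10 * log10(p50 / p30), 10 * log10(25) - 20)
  # idempotence: second pass changes RMS by < 1%
  flt <- function(x)
    canicoh:::fft_bandpass(x, sr, band_hz = c(1, 70),
                           notch_hz = c(50, 100, 150))
  x1 <- flt(rec$data[1, ])
  x2 <- flt(x1)
  mid <- seq(sr, length(x1) - sr)
  expect_lt(abs(sqrt(mean(x2[mid]^2)) - sqrt(mean(x1[mid]^2))) /
              sqrt(mean(x1[mid]^2)), 0.01)
})

test_that("tf_power localizes a post-onset component and normalizes", {
  sr <- 500
  set.seed(7)
  n_pre <- sr; n_post <- 2 * sr
  trials <- t(replicate(30, {
    x <- rnorm(n_pre + n_post) * 0.5
    x[(n_pre + 1):(n_pre + n_post)] <-
      x[(n_pre + 1):(n_pre + n_post)] +
      2 * sin(2 * pi * 3 * (seq_len(n_post)) / sr)
    x
  }))
  ep <- epoch_set(trials, sr, t0_s = -1)
  tfr <- tf_power(ep, freqs_hz = 1:20)
  peak <- which(tfr$power == max(tfr$power), arr.ind = TRUE)
  expect_equal(tfr$freqs_hz[peak[2]], 3)
  expect_gt(tfr$times_s[peak[1]], 0)
  # z-scored map has mean 0, SD 1
  tfz <- tf_power(ep, freqs_hz = 1:20, normalization = "zscore")
  expect_equal(mean(tfz$power), 0, tolerance = 1e-12)
  expect_equal(stats::sd(as.numeric(tfz$power)), 1, tolerance = 1e-12)
  expect_error(tf_power(epoch_set(matrix(0, 0, 10))),
               class = "canicoh_invalid_input")
})

test_that("stationary noise gives ~zero mean relative power", {
  sr <- 500
  for (seed in 1:5) {
    set.seed(seed)
    ep <- epoch_set(matrix(rnorm(100 * 750), 100, 750), sr, t0_s = -0.5)
    tfr <- tf_power(ep, freqs_hz = seq(2, 30, by = 2),
                    baseline_window_s = c(-0.5, 0))
    expect_lt(abs(mean(tfr$power)), 0.05)
  }
})

test_that("peak_power_frequency: ground truth, tie rule, range, scaling", {
  env <- stream_env_500(1)
  # plant a 2.5 Hz locked component
  sr <- 500
  t <- seq(0, (length(env) - 1)) / sr
  env25 <- 1 + 0.8 * sin(2 * pi * 2.5 * t)
  ep <- gen_locked_eeg(locked_eeg_spec(env25, coupling = 3, n_trials = 15,
                                       band_hz = c(1, 7), seed = 2))
  tfr <- tf_power(ep, freqs_hz = seq(1, 10, by = 0.5))
  expect_equal(peak_power_frequency(tfr), 2.5, tolerance = 0.51)
  # constructed map: equal power everywhere -> lowest in-range frequency
  flat <- structure(list(times_s = seq(-1, 2, by = 0.01),
                         freqs_hz = 1:10,
                         power = matrix(1, 301, 10),
                         normalization = "relative"), class = "tfr")
  expect_equal(peak_power_frequency(flat), 1)
  # strong out-of-range peak ignored
  spec9 <- flat
  spec9$power <- matrix(rep(c(1, 1, 2, rep(1, 5), 9, 1), each = 301),
                        301, 10)
  expect_equal(peak_power_frequency(spec9, range_hz = c(1, 7)), 3)
  # invariant to global power scaling
  spec9b <- spec9
  spec9b$power <- spec9$power * 1e4
  expect_equal(peak_power_frequency(spec9b, range_hz = c(1, 7)), 3)
  expect_error(peak_power_frequency(spec9, window_s = c(90, 99)),
               class = "canicoh_invalid_argument")
})

test_that("decode_envelope: noiseless recovery, misalignment control, and
          errors", {
  env <- aperiodic_env_500()
  # trials = literally lag-shifted envelope, (almost) no noise
  sig <- c(rep(0, 25), env)[seq_along(env)]
  set.seed(4)
  tr <- rbind(sig, sig, sig) +
    1e-6 * matrix(rnorm(3 * length(sig)), nrow = 3)
  ep <- epoch_set(tr, 500, t0_s = 0)
  dec <- decode_envelope(ep, env, ridge_lambda = 1e-2)
  expect_gt(dec$r, 0.9)
  # reversing epochs in time destroys the fit (> 50% drop)
  ep_rev <- ep
  ep_rev$trials <- ep$trials[, rev(seq_len(ncol(ep$trials)))]
  dec_rev <- decode_envelope(ep_rev, env, ridge_lambda = 1e-2)
  expect_lt(dec_rev$r, 0.5 * dec$r)
  # same control in the noisy regime
  epn <- gen_locked_eeg(locked_eeg_spec(env, coupling = 2, n_trials = 8,
                                        seed = 1))
  epn_rev <- epn
  epn_rev$trials <- epn$trials[, rev(seq_len(ncol(epn$trials)))]
  r_f <- decode_envelope(epn, env, ridge_lambda = 100)$r
  r_r <- decode_envelope(epn_rev, env, ridge_lambda = 100)$r
  expect_lt(r_r, 0.5 * r_f)
  expect_error(decode_envelope(epoch_set(ep$trials[1, , drop = FALSE]),
                               env),
               class = "canicoh_insufficient_data")
})

test_that("decode_envelope null simulation stays near zero and r grows
          with coupling", {
  env <- stream_env_500(2)
  r0 <- vapply(1:10, function(s) {
    ep <- gen_locked_eeg(locked_eeg_spec(env, coupling = 0, n_trials = 6,
                                         seed = s))
    decode_envelope(ep, env, ridge_lambda = 100)$r
  }, 0)
  expect_lt(abs(mean(r0)), 0.1)
  # monotone mean r over a 3-point coupling grid
  rbar <- vapply(c(0.3, 1, 3), function(cp) {
    mean(vapply(1:8, function(s) {
      ep <- gen_locked_eeg(locked_eeg_spec(env, coupling = cp,
                                           n_trials = 6, seed = s))
      decode_envelope(ep, env, ridge_lambda = 100)$r
    }, 0))
  }, 0)
  expect_true(all(diff(rbar) > 0))
})
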