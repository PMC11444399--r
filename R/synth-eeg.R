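# Synthetic EEG with a controllable envelope-locked component, plus the
# paired speech-register table generator. Test harness for the coherence,
# decoding, and paired-statistics pipelines.

#' Specification of envelope-locked synthetic EEG
#'
#' Each trial is `coupling` x (band-passed, lag-shifted stimulus envelope,
#' unit variance) + 1/f^`noise_exponent` background noise (unit variance),
#' so `coupling` is the amplitude SNR of the locked component.
#'
#' @param envelope stimulus envelope time series at `sample_rate`
#'   (covering stimulus time t >= 0).
#' @param coupling coupling gain in `[0, Inf)`; 0 means pure noise.
#' @param lag_s neural lag of the locked component (s).
#' @param band_hz length-2 pass band of the locked component (Hz).
#' @param n_trials number of trials (>= 1).
#' @param noise_exponent spectral slope of the 1/f background.
#' @param baseline_s pre-stimulus baseline included in each epoch (s).
#' @param sample_rate sampling rate (Hz), 500 by default.
#' @param seed integer RNG seed.
#' @return an object of class `locked_eeg_spec`.
#' @export
locked_eeg_spec <- function(envelope, coupling = 1, lag_s = 0.05,
                            band_hz = c(1, 7), n_trials = 20,
                            noise_exponent = 1, baseline_s = 1,
                            sample_rate = 500, seed = 1L) {
  if (length(envelope) < 2)
    abort_canicoh("envelope must be a non-empty time series",
                  "canicoh_invalid_input")
  if (!is.numeric(coupling) || coupling < 0)
    abort_canicoh("coupling must be >= 0", "canicoh_invalid_spec")
  if (n_trials < 1)
    abort_canicoh("n_trials must be >= 1", "canicoh_invalid_spec")
  structure(list(envelope = as.numeric(envelope), coupling = coupling,
                 lag_s = lag_s, band_hz = band_hz,
                 n_trials = as.integer(n_trials),
                 noise_exponent = noise_exponent, baseline_s = baseline_s,
                 sample_rate = sample_rate, seed = as.integer(seed)),
            class = "locked_eeg_spec")
}

# 1/f^a noise, unit SD: white Gaussian spectrum shaped by f^(-a/2).
one_over_f_noise <- function(n, fs, exponent = 1) {
  w <- stats::rnorm(n)
  if (exponent == 0) return(w)
  W <- stats::fft(w)
  f <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) * fs / n
  shape <- c(0, abs(f[-1])^(-exponent / 2))
  x <- Re(stats::fft(W * shape, inverse = TRUE) / n)
  x / stats::sd(x)
}

#' Generate envelope-locked synthetic EEG epochs
#'
#' Epochs span `[-baseline_s, duration(envelope)]`; the locked component is
#' present from stimulus onset (t = 0), shifted by the neural lag.
#'
#' @param spec a [locked_eeg_spec()].
#' @return an [epoch_set] whose metadata records the ground truth.
#' @export
gen_locked_eeg <- function(spec) {
  if (!inherits(spec, "locked_eeg_spec"))
    abort_canicoh("`spec` must be a locked_eeg_spec", "canicoh_invalid_spec")
  sr <- spec$sample_rate
  env <- spec$envelope
  n_post <- length(env)
  n_pre <- round(spec$baseline_s * sr)
  n_tot <- n_pre + n_post
  # locked component: band-passed, lag-shifted envelope at unit variance
  sig <- butter_filtfilt(env - mean(env), sr, spec$band_hz, "pass", 4L)
  lag_n <- round(spec$lag_s * sr)
  sig <- c(rep(0, max(lag_n, 0)), sig)[seq_len(n_post)]
  s <- stats::sd(sig)
  if (s > 0) sig <- sig / s
  with_seed(spec$seed, {
    trials <- matrix(0, spec$n_trials, n_tot)
    for (k in seq_len(spec$n_trials)) {
      noise <- one_over_f_noise(n_tot, sr, spec$noise_exponent)
      trials[k, ] <- noise
      if (spec$coupling > 0)
        trials[k, (n_pre + 1):n_tot] <-
          trials[k, (n_pre + 1):n_tot] + spec$coupling * sig
    }
    epoch_set(trials, sample_rate = sr, t0_s = -spec$baseline_s,
              condition = rep("synthetic", spec$n_trials),
              meta = list(coupling = spec$coupling, lag_s = spec$lag_s,
                          band_hz = spec$band_hz, seed = spec$seed,
                          generator = "gen_locked_eeg"))
  })
}

#' Generate a paired speech-register table
#'
#' Emulates a table of matched adult-directed (ADS) and dog-directed (DDS)
#' sentences from the same speakers, with a known mean slowdown of DDS
#' relative to ADS and a known pitch (F0) elevation of DDS. Defaults encode
#' the registers reported for matched speakers: ADS ~4 syllables/s vs DDS
#' ~3 Hz (paired Cohen's d = 0.8) and a DDS F0 elevation with d = 0.6.
#'
#' @param n_pairs number of speakers (>= 2).
#' @param rate_effect_hz mean ADS - DDS speech-rate difference (Hz).
#' @param sd_hz SD of the within-pair rate difference (Hz).
#' @param f0_effect_hz mean DDS - ADS F0 difference (Hz).
#' @param f0_sd_hz SD of the within-pair F0 difference (Hz).
#' @param seed integer RNG seed.
#' @return data.frame(speaker, ads_rate_hz, dds_rate_hz, ads_f0_hz,
#'   dds_f0_hz).
#' @export
gen_paired_speech_table <- function(n_pairs = 12, rate_effect_hz = 1,
                                    sd_hz = 1.25, f0_effect_hz = 40,
                                    f0_sd_hz = 66, seed = 1L) {
  if (!is.numeric(n_pairs) || n_pairs < 2)
    abort_canicoh("n_pairs must be >= 2", "canicoh_invalid_spec")
  with_seed(seed, {
    ads_rate <- stats::rnorm(n_pairs, 4, 0.5)
    dds_rate <- ads_rate - stats::rnorm(n_pairs, rate_effect_hz, sd_hz)
    ads_f0 <- stats::rnorm(n_pairs, 180, 30)
    dds_f0 <- ads_f0 + stats::rnorm(n_pairs, f0_effect_hz, f0_sd_hz)
    data.frame(speaker = sprintf("spk%02d", seq_len(n_pairs)),
               ads_rate_hz = ads_rate, dds_rate_hz = dds_rate,
               ads_f0_hz = ads_f0, dds_f0_hz = dds_f0)
  })
}
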