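#' Morlet continuous wavelet transform
#'
#' Complex analytic Morlet decomposition evaluated by circular FFT
#' convolution. The wavelet at frequency `f` has a Gaussian frequency
#' response centred on `f` with temporal SD `n_cycles / (2 pi f)`; unit
#' L2 normalization. Circular convolution is deliberate: a circular time
#' shift of the input then commutes *exactly* with the transform, which the
#' surrogate-null machinery relies on.
#'
#' @param x numeric signal.
#' @param fs sampling rate (Hz).
#' @param freqs frequency grid (Hz).
#' @param n_cycles wavelet width in cycles (default 6).
#' @param t_index optional integer sample indices at which to keep
#'   coefficients (time decimation); default all samples. May index into
#'   the zero-padded region when `n_fft` extends the signal.
#' @param n_fft transform length; default the next 5-smooth length at or
#'   above `length(x)` (fast FFT). Pass `length(x)` for a strictly
#'   circular transform at native length.
#' @return complex matrix, `length(freqs)` x `length(t_index)`.
#' @keywords internal
morlet_cwt <- function(x, fs, freqs, n_cycles = 6, t_index = NULL,
                       n_fft = NULL) {
  n <- length(x)
  if (n < 2) abort_canicoh("signal too short for CWT", "canicoh_invalid_input")
  if (is.null(n_fft)) n_fft <- stats::nextn(n, c(2, 3, 5))
  if (is.null(t_index)) t_index <- seq_len(n)
  if (n_fft > n) x <- c(x, numeric(n_fft - n))
  n <- n_fft
  X <- stats::fft(x)
  # FFT bin frequencies (two-sided)
  fgrid <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) * fs / n
  out <- matrix(0 + 0i, length(freqs), length(t_index))
  for (i in seq_along(freqs)) {
    f <- freqs[i]
    sigma_t <- n_cycles / (2 * pi * f)
    # analytic wavelet: Gaussian on positive frequencies only
    # unit peak gain: a spectral line at f keeps its amplitude regardless
    # of f (no 1/f power tilt, so modulation-spectrum peaks are unbiased)
    H <- exp(-0.5 * ((fgrid - f) * 2 * pi * sigma_t)^2)
    H[fgrid < 0] <- 0
    w <- stats::fft(X * H, inverse = TRUE) / n
    out[i, ] <- w[t_index]
  }
  out
}
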