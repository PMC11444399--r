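# Minimal Butterworth IIR design (zpk -> second-order sections) and
# zero-phase filtering, plus the FFT Hilbert transform. Designs follow the
# textbook analog-prototype / frequency-transform / bilinear route; section
# filtering runs in C++ (sosfilt_cpp). Coefficients are cross-checked in the
# test suite against values frozen from an independent implementation.

# Analog Butterworth prototype: n poles on the unit circle, no zeros, gain 1.
butter_prototype <- function(n) {
  k <- seq_len(n)
  p <- exp(1i * pi * (2 * k + n - 1) / (2 * n))
  # force exact conjugate symmetry (odd n has a real pole at -1)
  if (n %% 2 == 1) p[(n + 1) / 2] <- -1 + 0i
  list(z = complex(0), p = p, k = 1)
}

lp2lp_zpk <- function(zpk, wo) {
  list(z = zpk$z * wo, p = zpk$p * wo,
       k = zpk$k * wo^(length(zpk$p) - length(zpk$z)))
}

lp2hp_zpk <- function(zpk, wo) {
  degree <- length(zpk$p) - length(zpk$z)
  z <- wo / zpk$z
  p <- wo / zpk$p
  z <- c(z, rep(0 + 0i, degree))
  k <- zpk$k * Re(prod(-zpk$z) / prod(-zpk$p))
  list(z = z, p = p, k = k)
}

lp2bp_zpk <- function(zpk, wo, bw) {
  degree <- length(zpk$p) - length(zpk$z)
  zlp <- zpk$z * bw / 2
  plp <- zpk$p * bw / 2
  z <- c(zlp + sqrt(zlp^2 - wo^2), zlp - sqrt(zlp^2 - wo^2),
         rep(0 + 0i, degree))
  p <- c(plp + sqrt(plp^2 - wo^2), plp - sqrt(plp^2 - wo^2))
  list(z = z, p = p, k = zpk$k * bw^degree)
}

lp2bs_zpk <- function(zpk, wo, bw) {
  degree <- length(zpk$p) - length(zpk$z)
  zhp <- (bw / 2) / zpk$z
  php <- (bw / 2) / zpk$p
  z <- c(zhp + sqrt(zhp^2 - wo^2), zhp - sqrt(zhp^2 - wo^2))
  p <- c(php + sqrt(php^2 - wo^2), php - sqrt(php^2 - wo^2))
  z <- c(z, rep(1i * wo, degree), rep(-1i * wo, degree))
  k <- zpk$k * Re(prod(-zpk$z) / prod(-zpk$p))
  list(z = z, p = p, k = k)
}

bilinear_zpk <- function(zpk, fs) {
  fs2 <- 2 * fs
  degree <- length(zpk$p) - length(zpk$z)
  zd <- (fs2 + zpk$z) / (fs2 - zpk$z)
  pd <- (fs2 + zpk$p) / (fs2 - zpk$p)
  zd <- c(zd, rep(-1 + 0i, degree))
  k <- zpk$k * Re(prod(fs2 - zpk$z) / prod(fs2 - zpk$p))
  list(z = zd, p = pd, k = k)
}

#' Butterworth digital filter design (second-order sections)
#'
#' @param n filter order (doubled internally for band-pass/stop).
#' @param w cutoff (Hz): scalar for low/high-pass, length-2 for band filters.
#' @param fs sampling rate (Hz).
#' @param type one of "low", "high", "pass", "stop".
#' @return a matrix with one row per biquad (b0 b1 b2 1 a1 a2).
#' @keywords internal
butter_sos <- function(n, w, fs, type = c("low", "high", "pass", "stop")) {
  type <- match.arg(type)
  wn <- w / (fs / 2)
  if (any(wn <= 0) || any(wn >= 1))
    abort_canicoh("filter cutoff must lie strictly inside (0, Nyquist)",
                  "canicoh_invalid_input")
  proto <- butter_prototype(n)
  fs_b <- 2
  warped <- 2 * fs_b * tan(pi * wn / fs_b)
  zpk <- switch(type,
    low  = lp2lp_zpk(proto, warped),
    high = lp2hp_zpk(proto, warped),
    pass = lp2bp_zpk(proto, sqrt(prod(warped)), diff(warped)),
    stop = lp2bs_zpk(proto, sqrt(prod(warped)), diff(warped)))
  zpk2sos(bilinear_zpk(zpk, fs_b))
}

# Pair conjugate poles/zeros into biquads. Poles sorted by closeness to the
# unit circle (worst first paired last so the gain distributes benignly);
# each pole pair takes the closest remaining zero pair.
zpk2sos <- function(zpk) {
  z <- zpk$z; p <- zpk$p; k <- zpk$k
  np <- length(p)
  if (np == 0) return(matrix(c(k, 0, 0, 1, 0, 0), nrow = 1))
  if (length(z) < np) z <- c(z, rep(0 + 0i, np - length(z)))
  pair_up <- function(r) {
    # order roots into conjugate (or real) pairs
    r <- r[order(Re(r), abs(Im(r)))]
    used <- rep(FALSE, length(r))
    pairs <- list()
    for (i in seq_along(r)) {
      if (used[i]) next
      used[i] <- TRUE
      if (abs(Im(r[i])) < 1e-10) {
        j <- which(!used & abs(Im(r)) < 1e-10)[1]
        if (is.na(j)) { pairs[[length(pairs) + 1]] <- c(r[i], NA); next }
      } else {
        j <- which(!used & abs(r - Conj(r[i])) < 1e-8)[1]
        if (is.na(j)) j <- which(!used)[which.min(abs(r[!used] - Conj(r[i])))]
      }
      used[j] <- TRUE
      pairs[[length(pairs) + 1]] <- c(r[i], r[j])
    }
    pairs
  }
  ppairs <- pair_up(p)
  zpairs <- pair_up(z)
  # sort pole pairs: nearest the unit circle first
  pd <- vapply(ppairs, function(pp) min(abs(1 - abs(pp)), na.rm = TRUE), 0)
  ppairs <- ppairs[order(pd)]
  sos <- matrix(0, length(ppairs), 6)
  for (i in seq_along(ppairs)) {
    pp <- ppairs[[i]]
    # pick the zero pair closest to this pole pair
    if (length(zpairs)) {
      zd <- vapply(zpairs, function(zz)
        sum(abs(zz[!is.na(zz)] - pp[1])), 0)
      j <- which.min(zd)
      zz <- zpairs[[j]]; zpairs[[j]] <- NULL
    } else zz <- c(NA, NA)
    poly2 <- function(rr) {
      rr <- rr[!is.na(rr)]
      if (length(rr) == 0) return(c(1, 0, 0))
      if (length(rr) == 1) return(c(1, -Re(rr), 0))
      c(1, -Re(rr[1] + rr[2]), Re(rr[1] * rr[2]))
    }
    sos[i, 1:3] <- poly2(zz)
    sos[i, 4:6] <- poly2(pp)
  }
  sos[1, 1:3] <- sos[1, 1:3] * k
  sos
}

# steady-state initial conditions for one biquad (step response scaling)
biquad_zi <- function(sec) {
  b <- sec[1:3]; a <- sec[4:6]
  A <- matrix(c(1 + a[2], -1, a[3], 1), 2, 2, byrow = TRUE)
  B <- c(b[2] - a[2] * b[1], b[3] - a[3] * b[1])
  solve(A, B)
}

sosfilt <- function(sos, x, zi_scale = 0) {
  zi <- matrix(0, nrow(sos), 2)
  if (!identical(zi_scale, 0)) {
    x0 <- zi_scale
    for (s in seq_len(nrow(sos))) {
      zi[s, ] <- biquad_zi(sos[s, ]) * x0
      # steady-state output of this section for constant input x0
      x0 <- x0 * sum(sos[s, 1:3]) / sum(c(1, sos[s, 5:6]))
    }
  }
  .Call(C_sosfilt, sos, as.numeric(x), zi)
}

#' Zero-phase (forward-backward) filtering
#'
#' Odd-reflection padding plus steady-state initial conditions, applied
#' forward and backward so the net filter has zero group delay.
#' @keywords internal
sosfiltfilt <- function(sos, x) {
  n <- length(x)
  # pad past the slowest transient: ~6 time constants of the outermost pole
  maxr <- sqrt(max(pmin(abs(sos[, 6]), 0.999999)))
  padlen <- min(n - 1L, max(18L * nrow(sos), ceiling(6 / max(1 - maxr, 1e-4))))
  if (padlen < 1)
    abort_canicoh("signal too short to filter", "canicoh_invalid_input")
  pre <- 2 * x[1] - x[seq(padlen + 1, 2)]
  post <- 2 * x[n] - x[seq(n - 1, n - padlen)]
  ext <- c(pre, x, post)
  y <- sosfilt(sos, ext, zi_scale = ext[1])
  y <- rev(sosfilt(sos, rev(y), zi_scale = y[length(y)]))
  y[seq(padlen + 1, padlen + n)]
}

butter_filtfilt <- function(x, fs, w, type, order = 4L) {
  sosfiltfilt(butter_sos(order, w, fs, type), x)
}

#' Zero-phase frequency-domain (DFT) filtering
#'
#' Multiplies the spectrum by a mask that is 1 in the pass region, 0 in the
#' stop region, with raised-cosine transitions of width `transition_hz`.
#' Exactly zero-phase and (outside the narrow transitions) idempotent.
#' `band_hz` gives the pass band; `notch_hz` lists centre frequencies whose
#' `+- notch_halfwidth_hz` neighbourhood is removed.
#' @keywords internal
fft_bandpass <- function(x, fs, band_hz = NULL, notch_hz = NULL,
                         notch_halfwidth_hz = 1, transition_hz = 0.5) {
  n <- length(x)
  f <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) * fs / n
  af <- abs(f)
  ramp_up <- function(edge)  # 0 below edge-tr, 1 above edge
    pmin(pmax((af - (edge - transition_hz)) / transition_hz, 0), 1)
  H <- rep(1, n)
  if (!is.null(band_hz)) {
    H <- H * ramp_up(band_hz[1])
    H <- H * (1 - ramp_up(band_hz[2] + transition_hz))
  }
  for (f0 in notch_hz) {
    if (f0 >= fs / 2) next
    inside <- pmin(pmax((af - (f0 - notch_halfwidth_hz - transition_hz)) /
                          transition_hz, 0), 1) *
      pmin(pmax(((f0 + notch_halfwidth_hz + transition_hz) - af) /
                  transition_hz, 0), 1)
    H <- H * (1 - inside)
  }
  # raised-cosine shaping of the linear ramps
  H <- ifelse(H <= 0, 0, ifelse(H >= 1, 1, 0.5 - 0.5 * cos(pi * H)))
  Re(stats::fft(stats::fft(x) * H, inverse = TRUE) / n)
}

#' Analytic signal via the FFT Hilbert transform
#' @keywords internal
hilbert_analytic <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Welch-averaged one-sided power spectrum (Hann, 50% overlap).
welch_psd <- function(x, fs, nfft = NULL, seg = NULL) {
  n <- length(x)
  if (is.null(seg)) seg <- min(n, 2^floor(log2(max(n / 4, 256))))
  if (is.null(nfft)) nfft <- max(seg, 2^ceiling(log2(seg)))
  hop <- max(1L, floor(seg / 2))
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg) / (seg + 1))
  starts <- seq(1L, max(1L, n - seg + 1L), by = hop)
  acc <- numeric(nfft %/% 2 + 1)
  for (s in starts) {
    xx <- x[s:(s + seg - 1L)] * win
    X <- stats::fft(c(xx, numeric(nfft - seg)))
    acc <- acc + Mod(X[seq_len(nfft %/% 2 + 1)])^2
  }
  list(freq = (seq_len(nfft %/% 2 + 1) - 1) * fs / nfft,
       power = acc / length(starts))
}
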