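# Internal spectral helpers shared by the respiration and coupling stages.

hann_window <- function(n) {
  if (n == 1L) return(1)
  0.5 * (1 - cos(2 * pi * (seq_len(n) - 1L) / (n - 1L)))
}

# Frequency-domain band-pass with raised-cosine transitions. Zero-phase by
# construction (real, symmetric gain). `x` is a numeric matrix (channels in
# columns). Gain is 1 on [lo, hi] and rolls off to 0 at lo - trans / hi +
# trans. When `analytic = TRUE` the negative frequencies are zeroed and the
# positive ones doubled, so the result is the complex analytic signal of the
# band-passed input and Mod() of it is the instantaneous amplitude.
fft_bandpass <- function(x, fs, lo, hi, trans = NULL, analytic = FALSE) {
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  if (is.null(trans)) trans <- 0.25 * (hi - lo)
  trans <- rep(trans, length.out = 2)  # c(lower-edge, upper-edge) widths
  n <- nrow(x)
  nfft <- stats::nextn(n, c(2, 3, 5))
  x[is.na(x)] <- 0
  xp <- rbind(x, matrix(0, nfft - n, ncol(x)))
  f <- c(seq(0, floor(nfft / 2)), seq(-ceiling(nfft / 2) + 1, -1)) * fs / nfft
  af <- abs(f)
  g <- numeric(nfft)
  lo0 <- max(lo - trans[1], 0)
  in_pass <- af >= lo & af <= hi
  in_lo <- af < lo & af > lo0
  in_hi <- af > hi & af < hi + trans[2]
  g[in_pass] <- 1
  if (trans[1] > 0) {
    g[in_lo] <- 0.5 * (1 + cos(pi * (lo - af[in_lo]) / trans[1]))
  }
  if (trans[2] > 0) {
    g[in_hi] <- 0.5 * (1 + cos(pi * (af[in_hi] - hi) / trans[2]))
  }
  if (analytic) {
    g <- g * (2 - (f == 0) - (nfft %% 2 == 0 & af == fs / 2))
    g[f < 0] <- 0
  }
  X <- stats::mvfft(xp) * g
  y <- stats::mvfft(X, inverse = TRUE) / nfft
  y <- y[seq_len(n), , drop = FALSE]
  if (analytic) y else Re(y)
}

# Hann-tapered DFT coefficients of a set of epochs at a single frequency.
# `epochs`: numeric matrix, one epoch per row. The taper-weighted mean is
# subtracted per epoch first: positive-valued signals (amplitude envelopes)
# otherwise leak DC into the lowest bins through the taper's main lobe.
# Returns a complex vector, one coefficient per epoch (kernel
# exp(-2*pi*i*f*t)).
dft_coef_epochs <- function(epochs, fs, f, taper = TRUE) {
  if (is.vector(epochs)) epochs <- matrix(epochs, nrow = 1)
  m <- ncol(epochs)
  tt <- (seq_len(m) - 1L) / fs
  w <- if (taper) hann_window(m) else rep(1, m)
  kern <- w * exp(-2i * pi * f * tt)
  a <- as.numeric(epochs %*% w) / sum(w)
  as.complex(epochs %*% kern) - a * sum(kern)
}

#' Narrowband instantaneous EEG amplitude
#'
#' Band-passes each channel around a carrier frequency and returns the
#' magnitude of the analytic signal (Hilbert envelope). The filter is a
#' zero-phase frequency-sampling band-pass with raised-cosine transitions of
#' width 25% of the bandwidth; the lower pass-band edge is clipped at 0.25 Hz.
#' Following the bandwidth rule used for cross-frequency coherence, the
#' bandwidth should equal the modulation frequency f1 under study (e.g. f1 =
#' 5 Hz implies a 5 Hz wide filter at f2).
#'
#' @param eeg a [time_series()] (any number of channels).
#' @param f2 carrier (centre) frequency in Hz.
#' @param bandwidth filter bandwidth in Hz (total width, f2 +/- bandwidth/2).
#' @return a `respac_ts` holding the per-channel envelope, same fs and t0.
#' @export
envelope <- function(eeg, f2, bandwidth) {
  stopifnot(inherits(eeg, "respac_ts"))
  lo <- f2 - bandwidth / 2
  hi <- f2 + bandwidth / 2
  nyq <- eeg$fs / 2
  if (lo <= 0 || hi >= nyq) {
    stop(sprintf(
      "envelope band [%g, %g] Hz outside (0, Nyquist = %g) Hz", lo, hi, nyq
    ))
  }
  lo <- max(lo, 0.25)
  env <- Mod(fft_bandpass(eeg$samples, eeg$fs, lo, hi, analytic = TRUE))
  time_series(env, fs = eeg$fs, t0 = eeg$t0, labels = eeg$labels)
}

# Linear resampling of a single-channel signal onto arbitrary times.
resample_at <- function(ts, channel, times) {
  stats::approx(ts_times(ts), ts_channel(ts, channel), xout = times,
                rule = 2)$y
}
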