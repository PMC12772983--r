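## Internal spectral primitives.  All filtering is done in the frequency
## domain: multiplying the spectrum by the squared magnitude response of an
## analogue Butterworth design gives exactly the zero-phase (forward +
## backward) realisation without the numerical fragility of high-order IIR
## polynomials at the very low normalised frequencies used here
## (0.1 Hz at fs = 500 Hz).

## |absolute frequency| of each DFT bin
fft_bin_freqs <- function(n, fs) {
  f <- (0:(n - 1)) / n * fs
  idx <- f > fs / 2
  f[idx] <- fs - f[idx]
  f
}

## Squared magnitude of an order-`order` Butterworth band-pass
## (analogue prototype, lowpass-to-bandpass transformed).
butter_bandpass_mag2 <- function(f, low, high, order = 5) {
  f0sq <- low * high
  bw <- high - low
  x <- ifelse(f == 0, Inf, (f^2 - f0sq) / (f * bw))
  1 / (1 + x^(2 * order))
}

## Zero-phase band-pass of a numeric vector.
fft_bandpass <- function(x, fs, low, high, order = 5) {
  n <- length(x)
  H <- butter_bandpass_mag2(fft_bin_freqs(n, fs), low, high, order)
  Re(fft(fft(x) * H, inverse = TRUE)) / n
}

## Fourier resampling with a raised-cosine anti-alias taper rolling off
## between 70% and 90% of the target Nyquist frequency.
fft_resample <- function(x, fs, target_fs) {
  n <- length(x)
  m <- round(n * target_fs / fs)
  X <- fft(x)
  nf <- floor(m / 2)
  f <- (0:nf) * fs / n
  nyq <- target_fs / 2
  f1 <- 0.7 * nyq
  f2 <- 0.9 * nyq
  g <- ifelse(f <= f1, 1,
              ifelse(f >= f2, 0, 0.5 * (1 + cos(pi * (f - f1) / (f2 - f1)))))
  Y <- complex(m)
  Y[1:(nf + 1)] <- X[1:(nf + 1)] * g
  if (nf >= 2) Y[m - (1:(nf - 1)) + 1] <- Conj(Y[2:nf])
  if (m %% 2 == 0) Y[nf + 1] <- complex(real = Re(Y[nf + 1]))
  Re(fft(Y, inverse = TRUE)) / n
}

## Analytic signal via the frequency-domain Hilbert transformer.
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))

#' Welch power spectral density estimate
#'
#' One-sided PSD by averaging modified (Hann-tapered, mean-removed)
#' periodograms over 50%-overlapping segments.
#'
#' @param x numeric signal vector.
#' @param fs sampling rate in Hz.
#' @param nperseg segment length in samples (clamped to `length(x)`).
#' @param overlap fractional segment overlap in `[0, 1)`.
#' @return A list with `freq` (Hz) and `psd` (power per Hz).
#' @examples
#' s <- welch_psd(sin(2 * pi * 0.5 * seq(0, 120, by = 0.05)), fs = 20)
#' s$freq[which.max(s$psd)]
#' @export
welch_psd <- function(x, fs, nperseg = 1200, overlap = 0.5) {
  n <- length(x)
  if (n < 8) stopf("signal too short for PSD estimation (n = %d)", n)
  nperseg <- min(nperseg, n)
  step <- max(1, round(nperseg * (1 - overlap)))
  starts <- seq(1, n - nperseg + 1, by = step)
  w <- hann_window(nperseg)
  U <- sum(w^2)
  nf <- floor(nperseg / 2) + 1
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1)]
    seg <- (seg - mean(seg)) * w
    acc <- acc + Mod(fft(seg)[1:nf])^2
  }
  psd <- acc / (length(starts) * fs * U)
  if (nf > 2) psd[2:(nf - 1)] <- 2 * psd[2:(nf - 1)]
  list(freq = (0:(nf - 1)) * fs / nperseg, psd = psd)
}
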