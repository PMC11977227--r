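#' Welch power spectral density
#'
#' Averaged modified periodogram: the signal is split into Hann-tapered
#' segments of `min(length(x), 256)` samples with 50% overlap, each segment
#' is zero-padded to `nfft` points, and the squared FFT magnitudes are
#' averaged. The default `nfft` is the smallest power of two giving a
#' frequency grid of at most 0.25 bpm (1/240 Hz), which bounds the
#' quantization of spectral-peak heart-rate estimates.
#'
#' @param x numeric signal.
#' @param rate sampling rate in Hz.
#' @param nfft FFT length (zero-padded); default as described.
#' @return `list(freq, power)` over `[0, rate/2]`.
#' @export
welch_psd <- function(x, rate, nfft = NULL) {
  n <- length(x)
  if (n < 2L) stop_pv("signal too short for a PSD", class = "config_error")
  seg <- min(n, 256L)
  if (is.null(nfft)) nfft <- 2^ceiling(log2(max(4096, rate * 240)))
  step <- max(1L, seg %/% 2L)
  starts <- seq.int(1L, n - seg + 1L, by = step)
  taper <- 0.5 * (1 - cos(2 * pi * (0:(seg - 1)) / (seg - 1)))
  acc <- numeric(nfft)
  for (s in starts) {
    xs <- x[s:(s + seg - 1L)] * taper
    acc <- acc + Mod(stats::fft(c(xs, numeric(nfft - seg))))^2
  }
  half <- 1:(nfft %/% 2 + 1L)
  list(freq = (half - 1L) * rate / nfft, power = acc[half] / length(starts))
}

# Frequency (Hz) of the PSD maximum restricted to [band[1], band[2]].
spectral_peak_hz <- function(x, rate, band = c(0.65, 4.0)) {
  ps <- welch_psd(x, rate)
  in_band <- ps$freq >= band[1] & ps$freq <= band[2]
  p <- ps$power[in_band]
  if (all(p <= 0))
    stop_pv("power spectrum is zero in the pass band: undefined peak",
            class = "undefined_peak_error")
  ps$freq[in_band][which.max(p)]
}

# Fraction of in-band power concentrated within +-0.1 Hz of the component's
# own in-band peak; a periodicity score used to pick the pulse-carrying
# independent component.
peak_concentration <- function(x, rate, band = c(0.65, 4.0)) {
  ps <- welch_psd(x, rate)
  in_band <- ps$freq >= band[1] & ps$freq <= band[2]
  p <- ps$power[in_band]
  f <- ps$freq[in_band]
  if (all(p <= 0)) return(0)
  near <- abs(f - f[which.max(p)]) <= 0.1
  sum(p[near]) / sum(p)
}
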