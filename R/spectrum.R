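#' Welch-averaged power spectrum of a raw trace
#'
#' Power spectral density by Welch's method: the signal is cut into segments
#' of length `min(4096, N)` with 50% overlap, each segment is mean-detrended,
#' Hann-windowed and Fourier transformed, and the one-sided squared magnitudes
#' are averaged across segments. Operates on the raw (unsmoothed) trace.
#'
#' @param trace A [signal_trace] of length >= 64.
#' @param segment_length Segment length in samples (default `min(4096, N)`).
#' @return A `spectrum_result`: list with `freqs` (Hz, 0 to fs/2) and `power`
#'   (nonnegative PSD values), plus `fs`.
#' @export
power_spectrum <- function(trace, segment_length = NULL) {
  stopifnot(inherits(trace, "signal_trace"))
  x <- trace$samples
  n <- length(x)
  if (n < 64L) stop("power spectrum needs at least 64 samples, got ", n)
  L <- if (is.null(segment_length)) min(4096L, n) else as.integer(segment_length)
  stopifnot(L >= 8L, L <= n)
  hop <- max(1L, L %/% 2L)
  starts <- seq(1L, n - L + 1L, by = hop)
  w <- 0.5 * (1 - cos(2 * pi * (0:(L - 1L)) / (L - 1L)))  # Hann
  u <- sum(w^2)
  half <- L %/% 2L
  acc <- numeric(half + 1L)
  for (s in starts) {
    seg <- x[s:(s + L - 1L)]
    seg <- (seg - mean(seg)) * w
    sp <- abs(stats::fft(seg))^2
    one <- sp[1:(half + 1L)]
    # fold the negative frequencies into the positive side (except DC/Nyquist)
    if (half >= 2L) one[2:half] <- 2 * one[2:half]
    acc <- acc + one
  }
  psd <- acc / (length(starts) * u * trace$fs)
  structure(list(freqs = (0:half) * trace$fs / L, power = psd, fs = trace$fs),
            class = "spectrum_result")
}

#' @export
print.spectrum_result <- function(x, ...) {
  cat(sprintf("<spectrum_result> %d bins, 0-%.1f Hz, peak at %.2f Hz\n",
              length(x$freqs), max(x$freqs), x$freqs[which.max(x$power)]))
  invisible(x)
}

#' Fraction of spectral power in a frequency band
#'
#' Defaults to the alpha band (7.5-12.5 Hz), used to check that differences in
#' interval predictability are not a proxy for alpha-wave content.
#'
#' @param spectrum A `spectrum_result` from [power_spectrum].
#' @param band Numeric pair (low, high) in Hz.
#' @return Band power divided by total power, in `[0, 1]`.
#' @export
alpha_band_power <- function(spectrum, band = c(7.5, 12.5)) {
  stopifnot(inherits(spectrum, "spectrum_result"), length(band) == 2L,
            band[1] < band[2])
  if (band[1] > max(spectrum$freqs)) {
    stop("band [", band[1], ", ", band[2], "] Hz lies above the Nyquist frequency ",
         max(spectrum$freqs), " Hz")
  }
  sel <- spectrum$freqs >= band[1] & spectrum$freqs <= band[2]
  sum(spectrum$power[sel]) / sum(spectrum$power)
}
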