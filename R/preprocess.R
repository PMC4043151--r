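#' Gaussian smoothing configuration
#'
#' @param sigma Kernel standard deviation in samples. The default of 1 sample
#'   (10 ms at 100 Hz) removes sharp high-frequency peaks while leaving the
#'   1-2 Hz peak structure intact.
#' @param truncation Kernel half-width in multiples of `sigma` (default 4).
#' @return A `smoothing_config` list.
#' @export
smoothing_config <- function(sigma = 1, truncation = 4) {
  stopifnot(is.numeric(sigma), length(sigma) == 1L, sigma > 0,
            is.numeric(truncation), length(truncation) == 1L, truncation >= 1)
  structure(list(sigma = sigma, truncation = truncation),
            class = "smoothing_config")
}

#' Discretized, unit-sum Gaussian kernel
#'
#' Kernel weights on integer offsets in `[-ceil(truncation*sigma),
#' +ceil(truncation*sigma)]`, normalized to sum to one.
#'
#' @param config A [smoothing_config].
#' @return Numeric vector of kernel weights, odd length.
#' @export
gaussian_kernel <- function(config = smoothing_config()) {
  r <- as.integer(ceiling(config$truncation * config$sigma))
  w <- exp(-((-r:r)^2) / (2 * config$sigma^2))
  w / sum(w)
}

#' Smooth a trace with a Gaussian kernel
#'
#' Convolves the signal with the discretized Gaussian of [gaussian_kernel].
#' Boundaries are handled by reflect padding (the edge sample is mirrored
#' inclusively: `x[2], x[1] | x[1], x[2], ...`), which avoids the edge
#' attenuation that zero padding would cause and hence avoids spurious
#' boundary peaks. Output length equals input length.
#'
#' @param trace A [signal_trace].
#' @param config A [smoothing_config].
#' @return A smoothed [signal_trace] with unchanged metadata.
#' @export
gaussian_smooth <- function(trace, config = smoothing_config()) {
  stopifnot(inherits(trace, "signal_trace"))
  k <- gaussian_kernel(config)
  r <- (length(k) - 1L) %/% 2L
  x <- trace$samples
  n <- length(x)
  if (n <= length(k)) {
    stop("trace (", n, " samples) must be longer than the smoothing kernel (",
         length(k), " samples)")
  }
  xp <- c(x[r:1], x, x[n:(n - r + 1L)])
  sm <- stats::filter(xp, k, method = "convolution", sides = 2L)
  out <- as.numeric(sm[(r + 1L):(r + n)])
  trace$samples <- out
  trace
}

#' Detect strict local maxima
#'
#' Index `t` is a peak iff `x[t] > x[t-1]` and `x[t] > x[t+1]` (strict on both
#' sides). Endpoints are never peaks and plateaus (ties with a neighbor) yield
#' no peak. Indices are 1-based, following R convention.
#'
#' @param trace A [signal_trace] (length >= 3).
#' @return A `peak_series`: list with `indices` (strictly increasing integer
#'   sample indices) and `source_length`.
#' @export
detect_peaks <- function(trace) {
  stopifnot(inherits(trace, "signal_trace"))
  x <- trace$samples
  n <- length(x)
  if (n < 3L) stop("peak detection needs at least 3 samples, got ", n)
  i <- 2:(n - 1L)
  idx <- i[x[i] > x[i - 1L] & x[i] > x[i + 1L]]
  structure(list(indices = as.integer(idx), source_length = n),
            class = "peak_series")
}

#' @export
print.peak_series <- function(x, ...) {
  cat(sprintf("<peak_series> %d peaks over %d samples\n",
              length(x$indices), x$source_length))
  invisible(x)
}

#' Inter-peak intervals from detected peaks
#'
#' Differences between consecutive peak indices, kept in integer sample units;
#' conversion to milliseconds (`unit_ms = 1000/fs`, i.e. 10 ms per sample at
#' 100 Hz) happens only at reporting time.
#'
#' @param peaks A `peak_series` from [detect_peaks] (>= 2 peaks).
#' @param fs Sampling rate in Hz (fixes `unit_ms`).
#' @return An `ipi_series`: list with `intervals` (positive integers, length =
#'   number of peaks - 1) and `unit_ms`.
#' @export
compute_ipi <- function(peaks, fs = 100) {
  stopifnot(inherits(peaks, "peak_series"))
  if (length(peaks$indices) < 2L) {
    stop("need at least 2 peaks to form intervals, got ", length(peaks$indices))
  }
  structure(list(intervals = as.integer(diff(peaks$indices)),
                 unit_ms = 1000 / fs),
            class = "ipi_series")
}

#' Construct an IPI series from raw intervals
#'
#' Used by the synthetic generator and by tests; [compute_ipi] is the
#' extraction route from a signal.
#'
#' @param intervals Positive integer intervals in sample units.
#' @param unit_ms Milliseconds per sample (10 at 100 Hz).
#' @return An `ipi_series`.
#' @export
ipi_series <- function(intervals, unit_ms = 10) {
  intervals <- as.integer(intervals)
  stopifnot(length(intervals) >= 1L, all(intervals >= 1L))
  structure(list(intervals = intervals, unit_ms = unit_ms), class = "ipi_series")
}

#' @export
print.ipi_series <- function(x, ...) {
  cat(sprintf("<ipi_series> %d intervals, mean %.2f samples (%.1f ms)\n",
              length(x$intervals), mean(x$intervals),
              mean(x$intervals) * x$unit_ms))
  invisible(x)
}

#' Extract the IPI series from a raw trace
#'
#' Convenience chain: Gaussian smoothing, strict local-maximum detection, then
#' interval construction.
#'
#' @inheritParams gaussian_smooth
#' @return An `ipi_series`.
#' @export
extract_ipi <- function(trace, config = smoothing_config()) {
  compute_ipi(detect_peaks(gaussian_smooth(trace, config)), fs = trace$fs)
}
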