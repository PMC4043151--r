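#' State profile for the synthetic EEG generator
#'
#' Parameters of a single sleep/wake state's generative model: intervals
#' follow an AR(2) process with positively skewed (standardized lognormal)
#' innovations around a mean interval, and the waveform renders one
#' raised-cosine arc per cycle with Gaussian peak heights plus white
#' measurement noise.
#'
#' @param name State name: "REM", "AWAKE" or "SWS".
#' @param ipi_mean Mean interval in samples (>= 4).
#' @param ar_coeffs AR(2) coefficients on the mean-centered interval process;
#'   must lie inside the stationarity triangle.
#' @param innovation_sd SD of the interval innovations, in samples; this is
#'   the knob that sets one-step predictability (the optimal predictor's
#'   error floor).
#' @param amplitude_mean,amplitude_sd Peak height distribution (microvolts);
#'   `amplitude_mean` must exceed `3 * noise_sd` so peaks survive smoothing.
#' @param noise_sd Additive white measurement noise SD (microvolts).
#' @param ipi_skew Lognormal shape parameter of the innovations (> 0 gives
#'   positively skewed intervals).
#' @param slow_amplitude Amplitude (microvolts) of an additive slow sinusoidal
#'   oscillation with random phase, emulating the high-amplitude slow-wave
#'   regime; 0 disables it. Amplitudes whose slope rivals the arc curvature
#'   would displace peaks, so defaults stay well inside the recovery-safe
#'   range.
#' @param slow_freq Frequency of the slow oscillation (Hz).
#' @return A `state_profile` list.
#' @export
state_profile <- function(name, ipi_mean = 12, ar_coeffs = c(0.5, 0.2),
                          innovation_sd = 1, amplitude_mean = 20,
                          amplitude_sd = 4, noise_sd = 2, ipi_skew = 0.6,
                          slow_amplitude = 0, slow_freq = 0.75) {
  stopifnot(name %in% c("REM", "AWAKE", "SWS"),
            ipi_mean >= 4, innovation_sd >= 0, length(ar_coeffs) == 2L,
            amplitude_mean > 3 * noise_sd, amplitude_sd >= 0, noise_sd >= 0,
            ipi_skew >= 0, slow_amplitude >= 0, slow_freq > 0)
  if (!ar2_stationary(ar_coeffs)) {
    stop("AR coefficients (", ar_coeffs[1], ", ", ar_coeffs[2],
         ") lie outside the stationarity triangle")
  }
  structure(list(name = name, ipi_mean = ipi_mean, ar_coeffs = ar_coeffs,
                 innovation_sd = innovation_sd, amplitude_mean = amplitude_mean,
                 amplitude_sd = amplitude_sd, noise_sd = noise_sd,
                 ipi_skew = ipi_skew, slow_amplitude = slow_amplitude,
                 slow_freq = slow_freq),
            class = "state_profile")
}

ar2_stationary <- function(phi) {
  phi[2] > -1 && phi[1] + phi[2] < 1 && phi[2] - phi[1] < 1
}

#' Default three-state profiles
#'
#' Encodes the qualitative structure the analysis is designed to detect:
#' interval innovation noise ordered REM < AWAKE < SWS (0.6, 1.0, 2.5
#' samples), so that the conscious-state analogues are more predictable than
#' the slow-wave analogue. All states share a 12-sample (120 ms) mean
#' interval, AR(2) coefficients (0.5, 0.2) and lognormal shape 0.6; the SWS
#' profile gets larger peak amplitudes plus a 0.75 Hz slow oscillation,
#' mirroring the high-amplitude slow-wave regime and placing its dominant
#' spectral power below 3 Hz.
#'
#' @return Named list of three `state_profile` objects (REM, AWAKE, SWS).
#' @export
default_profiles <- function() {
  list(
    REM = state_profile("REM", innovation_sd = 0.6,
                        amplitude_mean = 20, amplitude_sd = 4, noise_sd = 1),
    AWAKE = state_profile("AWAKE", innovation_sd = 1.0,
                          amplitude_mean = 20, amplitude_sd = 4, noise_sd = 1),
    SWS = state_profile("SWS", innovation_sd = 2.5,
                        amplitude_mean = 60, amplitude_sd = 10, noise_sd = 1,
                        slow_amplitude = 8, slow_freq = 0.75)
  )
}

#' Generate a synthetic interval sequence
#'
#' Mean-centered AR(2) dynamics with standardized lognormal innovations:
#' `x_t = phi1 x_{t-1} + phi2 x_{t-2} + eta_t`, where `eta_t` is
#' `innovation_sd * (LN(0, ipi_skew) - E[LN]) / SD[LN]` (zero mean, SD
#' `innovation_sd`, positive skew). Intervals are `round(ipi_mean + x_t)`
#' clipped to a minimum of 2 samples.
#'
#' @param profile A [state_profile].
#' @param n Number of intervals (>= 10).
#' @param seed Integer RNG seed.
#' @return An `ipi_series` of `n` intervals.
#' @export
generate_ipi_sequence <- function(profile, n, seed = 1L) {
  stopifnot(inherits(profile, "state_profile"), n >= 10L)
  set.seed(seed)
  phi <- profile$ar_coeffs
  s <- profile$ipi_skew
  burn <- 100L
  m <- n + burn
  if (profile$innovation_sd == 0 || s == 0) {
    eta <- if (s == 0) stats::rnorm(m, 0, profile$innovation_sd) else numeric(m)
  } else {
    ln <- stats::rlnorm(m, 0, s)
    ln_mean <- exp(s^2 / 2)
    ln_sd <- sqrt((exp(s^2) - 1) * exp(s^2))
    eta <- profile$innovation_sd * (ln - ln_mean) / ln_sd
  }
  x <- numeric(m)
  for (t in 3:m) x[t] <- phi[1] * x[t - 1L] + phi[2] * x[t - 2L] + eta[t]
  x <- x[(burn + 1L):m]
  ipi_series(pmax(2L, as.integer(round(profile$ipi_mean + x))), unit_ms = 10)
}

#' Render a peak-structured waveform from an interval sequence
#'
#' Places peaks at cumulative interval positions (the first peak at sample 1)
#' and joins consecutive peaks with two raised-cosine half-arcs through a zero
#' trough at the interval midpoint, so every cycle contributes exactly one
#' strict local maximum before noise. Peak heights are drawn from
#' `N(amplitude_mean, amplitude_sd^2)` (floored at a tenth of the mean); if
#' the profile requests one, a slow sinusoid with random phase is added, and
#' finally white noise `N(0, noise_sd^2)`. Trace length is
#' `sum(intervals) + 1`; no padding beyond the final peak.
#'
#' @param intervals An `ipi_series` or integer vector of intervals (>= 2 each).
#' @param profile A [state_profile] (amplitudes, noise, state label).
#' @param seed Integer RNG seed for heights and noise.
#' @param subject_id Subject label carried into the trace.
#' @return A [signal_trace] at 100 Hz with the profile's state label.
#' @export
synthesize_signal <- function(intervals, profile, seed = 1L,
                              subject_id = "synthetic") {
  if (inherits(intervals, "ipi_series")) intervals <- intervals$intervals
  intervals <- as.integer(intervals)
  stopifnot(length(intervals) >= 1L, all(intervals >= 2L),
            inherits(profile, "state_profile"))
  set.seed(seed)
  pos <- cumsum(c(1L, intervals))
  n <- sum(intervals) + 1L
  heights <- stats::rnorm(length(pos), profile$amplitude_mean,
                          profile$amplitude_sd)
  heights <- pmax(heights, 0.1 * profile$amplitude_mean)
  x <- numeric(n)
  x[pos] <- heights
  for (j in seq_along(intervals)) {
    a <- pos[j]; b <- pos[j + 1L]
    d <- b - a
    h1 <- d %/% 2L             # descent a..a+h1 to the trough
    t1 <- seq_len(h1 - 1L)     # interior of descent (may be empty)
    if (length(t1)) x[a + t1] <- heights[j] * 0.5 * (1 + cos(pi * t1 / h1))
    x[a + h1] <- 0
    h2 <- d - h1               # ascent a+h1..b
    t2 <- seq_len(h2 - 1L)
    if (length(t2)) {
      x[a + h1 + t2] <- heights[j + 1L] * 0.5 * (1 - cos(pi * t2 / h2))
    }
  }
  if (profile$slow_amplitude > 0) {
    phase <- stats::runif(1, 0, 2 * pi)
    x <- x + profile$slow_amplitude *
      sin(2 * pi * profile$slow_freq * (0:(n - 1L)) / 100 + phase)
  }
  if (profile$noise_sd > 0) x <- x + stats::rnorm(n, 0, profile$noise_sd)
  signal_trace(x, fs = 100, channel = "synthetic",
               state = profile$name, subject_id = subject_id)
}

#' Simulate a full synthetic run (ground truth plus waveform)
#'
#' @param profile A [state_profile].
#' @param n_ipi Number of ground-truth intervals.
#' @param seed Integer RNG seed (intervals and waveform use derived seeds).
#' @param subject_id Subject label.
#' @return A `synthetic_run`: list with `profile`, `n_ipi`, `seed`, `true_ipi`
#'   (an `ipi_series`) and `trace` (a [signal_trace]).
#' @export
simulate_run <- function(profile, n_ipi, seed = 1L, subject_id = "synthetic") {
  true_ipi <- generate_ipi_sequence(profile, n_ipi, seed = seed)
  trace <- synthesize_signal(true_ipi, profile, seed = seed + 1L,
                             subject_id = subject_id)
  structure(list(profile = profile, n_ipi = as.integer(n_ipi),
                 seed = as.integer(seed), true_ipi = true_ipi, trace = trace),
            class = "synthetic_run")
}
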