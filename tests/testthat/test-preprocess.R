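test_that("smoothing is exact on constants and on an impulse", {
  cfg <- smoothing_config(sigma = 1, truncation = 4)
  const <- signal_trace(rep(3.7, 100))
  expect_equal(gaussian_smooth(const, cfg)$samples, rep(3.7, 100),
               tolerance = 1e-12)

  # unit impulse at the center of a long zero trace reproduces the kernel
  n <- 101L
  x <- numeric(n); x[51L] <- 1
  sm <- gaussian_smooth(signal_trace(x), cfg)$samples
  k <- gaussian_kernel(cfg)
  r <- (length(k) - 1L) %/% 2L
  expect_equal(sm[(51L - r):(51L + r)], k, tolerance = 1e-12)
  expect_equal(sum(abs(sm[-((51L - r):(51L + r))])), 0, tolerance = 1e-12)
})

test_that("smoothing is linear and matches a direct convolution oracle", {
  cfg <- smoothing_config(sigma = 1.5, truncation = 4)
  k <- gaussian_kernel(cfg)
  set.seed(11)
  for (rep in 1:5) {
    x <- rnorm(60); y <- rnorm(60)
    a <- runif(1, -2, 2); b <- runif(1, -2, 2)
    sx <- gaussian_smooth(signal_trace(x), cfg)$samples
    sy <- gaussian_smooth(signal_trace(y), cfg)$samples
    sxy <- gaussian_smooth(signal_trace(a * x + b * y), cfg)$samples
    expect_equal(sxy, a * sx + b * sy, tolerance = 1e-10)
    expect_equal(sx, direct_smooth(x, k), tolerance = 1e-12)
  }
  expect_error(gaussian_smooth(signal_trace(rnorm(5)), cfg), "longer")
})

test_that("peak detection follows the strict-neighbor definition", {
  expect_error(detect_peaks(signal_trace(c(1, 2))), "at least 3 samples")
  # strictly increasing trace has no interior maximum
  expect_length(detect_peaks(signal_trace(1:50))$indices, 0L)
  # [0, 1, 0, 2, 0] -> peaks at the 2nd and 4th samples
  expect_identical(detect_peaks(signal_trace(c(0, 1, 0, 2, 0)))$indices,
                   c(2L, 4L))
  # plateaus yield no peak
  expect_length(detect_peaks(signal_trace(c(0, 1, 1, 0)))$indices, 0L)
})

test_that("peak detection equals the brute-force definitional scan", {
  set.seed(99)
  for (rep in 1:20) {
    x <- rnorm(1000)
    expect_identical(detect_peaks(signal_trace(x))$indices,
                     brute_force_peaks(x))
  }
  # short traces, exhaustively random including ties
  for (rep in 1:50) {
    x <- sample(0:3, 10, replace = TRUE)
    expect_identical(detect_peaks(signal_trace(x))$indices,
                     brute_force_peaks(x))
  }
})

test_that("IPI construction subtracts peak indices and keeps sample units", {
  pk <- structure(list(indices = c(5L, 15L, 30L), source_length = 40L),
                  class = "peak_series")
  ipi <- compute_ipi(pk, fs = 100)
  expect_identical(ipi$intervals, c(10L, 15L))
  expect_equal(ipi$unit_ms, 10)
  expect_error(compute_ipi(structure(list(indices = 5L, source_length = 10L),
                                     class = "peak_series")),
               "at least 2 peaks")
  # intervals sum to the span between first and last peak
  set.seed(3)
  x <- rnorm(500)
  pks <- detect_peaks(signal_trace(x))
  ii <- compute_ipi(pks, 100)
  expect_identical(sum(ii$intervals),
                   pks$indices[length(pks$indices)] - pks$indices[1L])
})

test_that("sinusoid IPIs match the analytic period", {
  fs <- 100; f <- 2
  # phase offset keeps sampled maxima off exact two-sample plateaus
  tr <- signal_trace(sin(2 * pi * f * (0:9999) / fs + 0.3), fs = fs)
  ipi <- compute_ipi(detect_peaks(tr), fs)
  expect_lt(abs(mean(ipi$intervals) - fs / f), 1)
})

test_that("heavier smoothing does not create peaks", {
  set.seed(21)
  for (rep in 1:5) {
    base <- sin(2 * pi * 2 * (0:1999) / 100) * 20 + rnorm(2000, sd = 3)
    tr <- signal_trace(base)
    n1 <- length(detect_peaks(gaussian_smooth(tr, smoothing_config(sigma = 1)))$indices)
    n3 <- length(detect_peaks(gaussian_smooth(tr, smoothing_config(sigma = 3)))$indices)
    expect_lte(n3, n1)
  }
})
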