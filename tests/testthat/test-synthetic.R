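test_that("interval generator hits its limits: zero noise, determinism, skew", {
  p <- state_profile("AWAKE", innovation_sd = 0)
  expect_true(all(generate_ipi_sequence(p, 100, seed = 1)$intervals == 12L))

  p2 <- default_profiles()$AWAKE
  expect_identical(generate_ipi_sequence(p2, 500, seed = 9)$intervals,
                   generate_ipi_sequence(p2, 500, seed = 9)$intervals)

  expect_gt(skewness_g1(generate_ipi_sequence(p2, 10000, seed = 2)$intervals), 0)

  expect_error(state_profile("AWAKE", ar_coeffs = c(0.9, 0.5)),
               "stationarity")
})

test_that("default profiles order predictability REM < AWAKE < SWS", {
  profs <- default_profiles()
  sds <- vapply(profs[c("REM", "AWAKE", "SWS")], function(p) p$innovation_sd,
                numeric(1))
  expect_true(sds[["REM"]] < sds[["AWAKE"]] && sds[["AWAKE"]] < sds[["SWS"]])
  for (p in profs) {
    expect_s3_class(p, "state_profile")
    expect_gte(p$ipi_mean, 4)
    expect_gt(p$amplitude_mean, 3 * p$noise_sd)
    expect_true(ipipredict:::ar2_stationary(p$ar_coeffs))
  }
})

test_that("noiseless constant-interval rendering places exact, 2 Hz peaks", {
  p <- state_profile("AWAKE", noise_sd = 0, amplitude_sd = 0, amplitude_mean = 20)
  intervals <- rep(50L, 60)
  tr <- synthesize_signal(intervals, p, seed = 1)
  expect_length(tr$samples, sum(intervals) + 1)
  pk <- detect_peaks(gaussian_smooth(tr))
  placed <- cumsum(c(1L, intervals))
  placed <- placed[placed > 1 & placed < length(tr$samples)]
  expect_equal(length(pk$indices), length(placed))
  expect_lte(max(abs(pk$indices - placed)), 1)

  sp <- power_spectrum(tr)
  expect_equal(sp$freqs[which.max(sp$power)], 2, tolerance = 0.05)
})

test_that("noiseless traces reproduce the ground-truth intervals exactly", {
  for (state in c("REM", "AWAKE", "SWS")) {
    p <- default_profiles()[[state]]
    p$noise_sd <- 0
    true <- generate_ipi_sequence(p, 1500, seed = 41)$intervals
    tr <- synthesize_signal(true, p, seed = 42)
    rec <- compute_ipi(detect_peaks(tr), 100)$intervals
    # first and last placed peaks sit on the trace endpoints and are dropped
    expect_identical(rec, true[2:(length(true) - 1L)])
  }
})

test_that("recovery through smoothing stays above 95% exact at default noise", {
  for (state in c("REM", "AWAKE", "SWS")) {
    p <- default_profiles()[[state]]
    true <- generate_ipi_sequence(p, 2000, seed = 51)$intervals
    tr <- synthesize_signal(true, p, seed = 52)
    rec <- extract_ipi(tr)$intervals
    expect_length(rec, length(true) - 2L)
    expect_gte(mean(rec == true[2:(length(true) - 1L)]), 0.95)
  }
})

test_that("recovered interval distributions keep their positive skew", {
  for (state in c("REM", "AWAKE", "SWS")) {
    run <- simulate_run(default_profiles()[[state]], 2000, seed = 61)
    expect_gt(skewness_g1(extract_ipi(run$trace)$intervals), 0)
  }
})
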