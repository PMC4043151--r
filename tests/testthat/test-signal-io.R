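test_that("signal_trace enforces its invariants", {
  expect_error(signal_trace(1), "at least 2 samples")
  expect_error(signal_trace(c(1, NA, 3)), "non-finite")
  expect_error(signal_trace(c(1, Inf)), "non-finite")
  expect_error(signal_trace(1:5, fs = 0), "positive")
  tr <- signal_trace(1:5, fs = 100, state = "REM")
  expect_s3_class(tr, "signal_trace")
  expect_identical(length(tr), 5L)
})

test_that("text round trip preserves values to printed precision", {
  path <- withr::local_tempfile(fileext = ".txt")
  vals <- c(1.0, 2.0, 3.0)
  writeLines(c("1.0", "2.0", "3.0"), path)
  tr <- read_text(path, fs = 100)
  expect_equal(tr$samples, vals)
  expect_equal(tr$fs, 100)

  set.seed(42)
  tr2 <- signal_trace(rnorm(200) * 50, fs = 100, channel = "Fpz-Cz",
                      state = "SWS", subject_id = "s1")
  write_text(tr2, path)
  back <- read_text(path, fs = tr2$fs)
  expect_equal(back$samples, tr2$samples, tolerance = 1e-11)
  expect_length(back$samples, length(tr2$samples))
})

test_that("read_text reports the offending line and skips comments", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("1.0", "x"), path)
  expect_error(read_text(path, fs = 100), "line 2")
  writeLines(c("# header comment", "", "1.5", "2.5"), path)
  expect_equal(read_text(path, fs = 100)$samples, c(1.5, 2.5))
  expect_error(read_text(tempfile(), fs = 100), "not found")
})

test_that("EDF write-then-read round-trips within 16-bit quantization", {
  path <- withr::local_tempfile(fileext = ".edf")
  set.seed(7)
  n <- 1000
  a <- signal_trace(rnorm(n, sd = 40), fs = 100, channel = "Fpz-Cz")
  b <- signal_trace(sin(2 * pi * 2 * (0:(n - 1)) / 100) * 30, fs = 100,
                    channel = "Pz-Oz")
  write_edf(list(a, b), path)

  back <- read_edf(path, "Fpz-Cz")
  expect_equal(back$fs, 100)
  expect_length(back$samples, n)
  qstep <- (max(a$samples) - min(a$samples)) / 2^16
  expect_lt(max(abs(back$samples - a$samples)), qstep + 1e-12)

  back2 <- read_edf(path, "Pz-Oz")
  qstep2 <- (max(b$samples) - min(b$samples)) / 2^16
  expect_lt(max(abs(back2$samples - b$samples)), qstep2 + 1e-12)
})

test_that("EDF error paths name the available channels and reject junk", {
  path <- withr::local_tempfile(fileext = ".edf")
  a <- signal_trace(rnorm(100), fs = 100, channel = "Fpz-Cz")
  b <- signal_trace(rnorm(100), fs = 100, channel = "Pz-Oz")
  write_edf(list(a, b), path)
  err <- expect_error(read_edf(path, "Cz-Oz"), "not found")
  expect_match(conditionMessage(err), "Fpz-Cz")
  expect_match(conditionMessage(err), "Pz-Oz")

  empty <- withr::local_tempfile(fileext = ".edf")
  file.create(empty)
  expect_error(read_edf(empty, "Fpz-Cz"), "EDF")
  expect_error(read_edf(tempfile(), "Fpz-Cz"), "not found")
})
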