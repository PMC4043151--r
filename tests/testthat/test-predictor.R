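test_that("split_series forms chronological 60/15/25 windowed pairs", {
  ipi <- ipi_series(rep(c(10L, 12L, 14L), length.out = 110))
  ds <- split_series(ipi, window_config(k = 10))
  expect_equal(length(ds$targets), 100)
  expect_equal(as.integer(table(ds$split)), c(60L, 15L, 25L))
  # chronological: split tags are non-decreasing in time
  expect_identical(ds$split, sort(ds$split))

  ds2 <- split_series(ipi_series(1:12), window_config(k = 10, normalize = FALSE))
  expect_equal(length(ds2$targets), 2)
  expect_equal(as.numeric(ds2$inputs[1, ]), 1:10)
  expect_equal(ds2$targets[1], 11)

  expect_error(split_series(ipi_series(1:11), window_config(k = 10)),
               "at least")
})

test_that("pair count equals series length minus window length", {
  set.seed(5)
  for (rep in 1:10) {
    n <- sample(30:300, 1)
    k <- sample(1:12, 1)
    ipi <- ipi_series(sample(5:20, n, replace = TRUE))
    ds <- split_series(ipi, window_config(k = k))
    expect_equal(length(ds$targets), n - k)
    expect_equal(nrow(ds$inputs), n - k)
  }
})

test_that("normalization statistics come from the training portion only", {
  vals <- c(rep(10, 70), rep(100, 30))  # shift lives entirely in the TEST tail
  ds <- windowed_dataset(matrix(vals, ncol = 1), vals)
  tr_vals <- c(ds$inputs[ds$split == "TRAIN", 1], ds$targets[ds$split == "TRAIN"])
  expect_equal(mean(tr_vals), 0, tolerance = 1e-12)
  expect_equal(ds$norm_stats[["mean"]], 10)
})

test_that("LM drives a noiseless linear map to near-zero training error", {
  set.seed(31)
  n <- 300; k <- 10  # enough TRAIN residuals to exceed the parameter count
  X <- matrix(rnorm(n * k), n, k)
  y <- 0.5 * X[, k] + 1
  ds <- windowed_dataset(X, y)
  model <- train_lm(ds, training_config(max_epochs = 200, patience = 200,
                                        seed = 2))
  tr <- ds$split == "TRAIN"
  s <- ds$norm_stats[["sd"]]
  pred <- mlp_forward(model, ds$inputs[tr, ]) * s + ds$norm_stats[["mean"]]
  truth <- ds$targets[tr] * s + ds$norm_stats[["mean"]]
  expect_lt(mean((truth - pred)^2), 1e-6)
  expect_lte(model$trace$epochs, 200)

  # independent optimizer on the same residuals confirms zero is attainable
  ref_model <- mlp_model(k = k, hidden = 10, seed = 2)
  resid_fn <- function(theta) {
    m <- ipipredict:::unpack_params(ref_model, theta)
    ds$targets[tr] - mlp_forward(m, ds$inputs[tr, ])
  }
  fit <- minpack.lm::nls.lm(ipipredict:::pack_params(ref_model), fn = resid_fn,
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  expect_lt(mean(fit$fvec^2), 1e-6)
})

test_that("damping schedule uses the 0.1/10 factors and SSE never increases", {
  run <- study_arm("AWAKE", 101L)
  hist <- run$model$trace$history
  expect_true(all(diff(hist$train_sse) <= 0))
  # every accepted epoch ends with lambda = previous * 0.1 * 10^r, r >= 0
  lam <- c(0.001, hist$lambda)
  for (i in seq_len(nrow(hist))) {
    r <- log10(hist$lambda[i] / (lam[i] * 0.1))
    expect_equal(r, round(r), tolerance = 1e-9)
    expect_gte(round(r), 0)
  }
})

test_that("training is bit-reproducible under a fixed seed", {
  ipi <- generate_ipi_sequence(default_profiles()$AWAKE, 300, seed = 8)
  ds <- split_series(ipi)
  cfg <- training_config(seed = 4, max_epochs = 30, patience = 30)
  m1 <- train_lm(ds, cfg)
  m2 <- train_lm(ds, cfg)
  expect_identical(m1$W1, m2$W1)
  expect_identical(m1$w2, m2$w2)
  expect_identical(m1$trace$history, m2$trace$history)
})

test_that("heavily damped steps point along the negative gradient", {
  ipi <- generate_ipi_sequence(default_profiles()$AWAKE, 200, seed = 9)
  ds <- split_series(ipi)
  model <- mlp_model(k = ds$k, hidden = 10, seed = 3)
  tr <- ds$split == "TRAIN"
  jb <- ipipredict:::mlp_jacobian(model, ds$inputs[tr, ])
  r <- ds$targets[tr] - jb$yhat
  Jtr <- crossprod(jb$J, r)  # -gradient/2 of the SSE
  p <- length(Jtr)
  delta <- solve(crossprod(jb$J) + diag(1e8, p), Jtr)
  expect_gt(cor(as.numeric(delta), as.numeric(Jtr)), 0.999)
})

test_that("evaluation de-normalizes and obeys the error identities", {
  ipi <- generate_ipi_sequence(default_profiles()$REM, 400, seed = 12)
  ds <- split_series(ipi)
  model <- train_lm(ds, training_config(seed = 5, max_epochs = 40))
  er <- evaluate(model, ds)
  expect_equal(er$abs_errors, abs(er$signed_errors))
  expect_equal(length(er$signed_errors), sum(ds$split == "TEST"))
  expect_gte(mean(er$abs_errors), abs(mean(er$signed_errors)))
  # truth is back on the raw interval scale (integers, not z-scores)
  expect_equal(er$truth, round(er$truth))
  expect_gt(mean(er$truth), 5)

  # a constant-output model on a constant series predicts perfectly
  Xc <- matrix(5, 40, 3)
  dsc <- windowed_dataset(Xc, rep(5, 40), normalize = FALSE)
  mc <- mlp_model(k = 3, hidden = 2, seed = 1)
  mc$w2 <- rep(0, 2); mc$b2 <- 5
  expect_equal(evaluate(mc, dsc)$signed_errors, rep(0, sum(dsc$split == "TEST")))
})

test_that("test error shrinks toward the innovation scale with more data", {
  profile <- default_profiles()$REM  # innovation_sd 0.6
  errs <- sapply(c(150, 3000), function(n) {
    ipi <- generate_ipi_sequence(profile, n, seed = 77)
    ds <- split_series(ipi)
    m <- train_lm(ds, training_config(seed = 78))
    mean(evaluate(m, ds)$abs_errors)
  })
  expect_lte(errs[2], errs[1] * 1.05)
  # mean |error| of the optimal predictor is below E|N(0, sd)| + rounding;
  # the trained network should land within a factor of two of that scale
  expect_lt(errs[2], 2 * (sqrt(2 / pi) * 0.6 + 0.25))
})

test_that("model serialization round-trips weights and predictions", {
  path <- withr::local_tempfile(fileext = ".json")
  ipi <- generate_ipi_sequence(default_profiles()$AWAKE, 300, seed = 14)
  ds <- split_series(ipi)
  m <- train_lm(ds, training_config(seed = 6, max_epochs = 20))
  write_model(m, path)
  m2 <- read_model(path)
  expect_equal(m2$W1, m$W1)
  expect_equal(m2$norm_stats, m$norm_stats)
  X <- ds$inputs[1:5, ]
  expect_equal(mlp_forward(m2, X), mlp_forward(m, X))
})
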