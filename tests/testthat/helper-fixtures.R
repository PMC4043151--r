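# Shared fixtures: independent brute-force oracles and a cached copy of the
# default three-state study so several test files can interrogate it without
# re-training networks.

# Definitional peak scan, written independently of detect_peaks: loop over
# every interior index and apply the strict-neighbor test.
brute_force_peaks <- function(x) {
  out <- integer(0)
  for (t in 2:(length(x) - 1L)) {
    if (x[t] > x[t - 1L] && x[t] > x[t + 1L]) out <- c(out, t)
  }
  out
}

# Direct convolution oracle (reflect padding), independent of stats::filter.
direct_smooth <- function(x, kernel) {
  r <- (length(kernel) - 1L) %/% 2L
  n <- length(x)
  xp <- c(x[r:1], x, x[n:(n - r + 1L)])
  out <- numeric(n)
  for (i in seq_len(n)) {
    out[i] <- sum(kernel * xp[i:(i + 2L * r)])
  }
  out
}

random_trace <- function(n, fs = 100) {
  signal_trace(stats::rnorm(n), fs = fs)
}

# One (state, seed) arm of the default synthetic study: generate, extract,
# train, evaluate. Sized as in the headline analysis (3000 intervals).
run_state_arm <- function(state, seed, n_ipi = 3000) {
  profile <- default_profiles()[[state]]
  run <- simulate_run(profile, n_ipi, seed = seed)
  ipi <- extract_ipi(run$trace)
  dataset <- split_series(ipi)
  model <- train_lm(dataset, training_config(seed = seed + 7))
  errors <- evaluate(model, dataset)
  list(state = state, seed = seed, true_ipi = run$true_ipi, ipi = ipi,
       model = model, errors = errors)
}

# The full 3-state x 3-seed study, computed once per test session.
study_cache <- new.env(parent = emptyenv())
default_study <- function() {
  if (is.null(study_cache$runs)) {
    runs <- list()
    for (seed in c(101L, 202L, 303L)) {
      for (state in c("REM", "AWAKE", "SWS")) {
        runs[[paste(state, seed, sep = "_")]] <-
          run_state_arm(state, seed + match(state, c("REM", "AWAKE", "SWS")))
      }
    }
    study_cache$runs <- runs
  }
  study_cache$runs
}

study_seeds <- c(101L, 202L, 303L)
study_arm <- function(state, seed) default_study()[[paste(state, seed, sep = "_")]]
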