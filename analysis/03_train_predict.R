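#!/usr/bin/env Rscript
# Stage 3: one-step interval prediction. For every (subject, state) interval
# sequence: window with k = 10 lags, split 60/15/25 chronologically, train a
# fresh 10-10-1 tanh network with Levenberg-Marquardt (lambda0 = 0.001,
# factors 0.1 / 10, validation early stopping), and record the held-out
# signed errors (true - predicted, in sample units).

suppressMessages(library(ipipredict))

SEED <- 42L
ipi_dir <- "results/ipi"
out_dir <- "results/errors"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
dir.create("results/models", showWarnings = FALSE)

files <- list.files(ipi_dir, pattern = "_ipi\\.txt$")
stopifnot(length(files) > 0)

idx <- 0L
for (f in files) {
  idx <- idx + 1L
  parts <- strsplit(sub("_ipi\\.txt$", "", f), "_")[[1]]
  subj <- parts[1]; st <- parts[2]
  ipi <- ipi_series(as.integer(readLines(file.path(ipi_dir, f))))
  dataset <- split_series(ipi, window_config(k = 10))
  model <- train_lm(dataset, training_config(seed = SEED + 31L * idx))
  errors <- evaluate(model, dataset)
  writeLines(formatC(errors$signed_errors, format = "g", digits = 12),
             file.path(out_dir, sprintf("%s_%s_errors.txt", subj, st)))
  write_model(model, sprintf("results/models/%s_%s.json", subj, st))
  message(sprintf("%s/%s: %d TRAIN pairs, %d epochs (%s), test mean |e| = %.3f samples (%.1f ms)",
                  subj, st, sum(dataset$split == "TRAIN"), model$trace$epochs,
                  model$trace$stop_reason, mean(errors$abs_errors),
                  mean(errors$abs_errors) * 10))
}
message("trained ", idx, " networks (one per subject x state)")
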