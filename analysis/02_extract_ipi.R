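#!/usr/bin/env Rscript
# Stage 2: smooth each trace (Gaussian, sigma = 1 sample), detect strict local
# maxima, and build the inter-peak-interval sequences. Writes one interval
# file per condition plus a summary table, and reports how faithfully the
# extracted intervals reproduce the generator's ground truth.

suppressMessages(library(ipipredict))

data_dir <- "results/data"
out_dir <- "results/ipi"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

traces <- list.files(data_dir, pattern = "^s[0-9]+_(REM|AWAKE|SWS)\\.txt$")
stopifnot(length(traces) > 0)

rows <- list()
for (f in traces) {
  parts <- strsplit(sub("\\.txt$", "", f), "_")[[1]]
  subj <- parts[1]; st <- parts[2]
  trace <- read_text(file.path(data_dir, f), fs = 100, state = st,
                     subject_id = subj)
  ipi <- extract_ipi(trace, smoothing_config(sigma = 1))
  writeLines(as.character(ipi$intervals),
             file.path(out_dir, sprintf("%s_%s_ipi.txt", subj, st)))

  true <- as.integer(readLines(file.path(data_dir,
                                         sprintf("%s_%s_true_ipi.txt", subj, st))))
  inner <- true[2:(length(true) - 1L)]  # boundary peaks sit on trace endpoints
  agree <- if (length(ipi$intervals) == length(inner)) {
    mean(ipi$intervals == inner)
  } else NA_real_
  rows[[f]] <- data.frame(subject = subj, state = st,
                          n_intervals = length(ipi$intervals),
                          mean_samples = mean(ipi$intervals),
                          mean_ms = mean(ipi$intervals) * ipi$unit_ms,
                          skewness = skewness_g1(ipi$intervals),
                          exact_recovery = agree)
  message(sprintf("%s/%s: %d intervals, mean %.1f samples (%.0f ms), skewness %.2f, ground-truth agreement %.3f",
                  subj, st, length(ipi$intervals), mean(ipi$intervals),
                  mean(ipi$intervals) * ipi$unit_ms, skewness_g1(ipi$intervals),
                  agree))
}

tab <- do.call(rbind, rows)
dir.create("results/tables", showWarnings = FALSE)
write.table(tab, "results/tables/ipi_summary.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message("All interval distributions are positively skewed: ",
        all(tab$skewness > 0))
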