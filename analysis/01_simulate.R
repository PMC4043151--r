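#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study cohort.
#
# Four "subjects" x three states (REM, AWAKE, SWS), 3,000 ground-truth
# intervals each, mirroring the 12-condition grid of the EEG design. Each
# condition is written as a one-column text trace plus its ground-truth
# interval sequence, so later stages (and anyone auditing them) work from
# files alone.

suppressMessages(library(ipipredict))

SEED <- 42L
N_IPI <- 3000L
SUBJECTS <- paste0("s", 1:4)
STATES <- c("REM", "AWAKE", "SWS")

out_dir <- "results/data"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

profiles <- default_profiles()
idx <- 0L
for (subj in SUBJECTS) {
  for (st in STATES) {
    idx <- idx + 1L
    run <- simulate_run(profiles[[st]], N_IPI, seed = SEED + 13L * idx,
                        subject_id = subj)
    write_text(run$trace, file.path(out_dir, sprintf("%s_%s.txt", subj, st)))
    writeLines(as.character(run$true_ipi$intervals),
               file.path(out_dir, sprintf("%s_%s_true_ipi.txt", subj, st)))
    message(sprintf("%s/%s: %d samples (%.0f s at 100 Hz), true IPI mean %.1f samples, skewness %.2f",
                    subj, st, length(run$trace$samples),
                    length(run$trace$samples) / 100,
                    mean(run$true_ipi$intervals),
                    skewness_g1(run$true_ipi$intervals)))
  }
}
message("wrote ", idx, " traces to ", out_dir)
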