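#!/usr/bin/env Rscript
# Stage 4: cross-state statistics. Per condition: error moments and skewness.
# Per subject: Welch t-test and pooled-SD Cohen's d on log-transformed
# absolute errors for every state pair, ordered (SWS, AWAKE, REM) so positive
# d means the first-listed state is less predictable. Also Welch spectra of
# the raw traces and their alpha-band (7.5-12.5 Hz) power fractions.

suppressMessages(library(ipipredict))

err_dir <- "results/errors"
dir.create("results/tables", showWarnings = FALSE)

files <- list.files(err_dir, pattern = "_errors\\.txt$")
stopifnot(length(files) > 0)
errors <- list()
rows <- list()
for (f in files) {
  parts <- strsplit(sub("_errors\\.txt$", "", f), "_")[[1]]
  subj <- parts[1]; st <- parts[2]
  e <- as.numeric(readLines(file.path(err_dir, f)))
  errors[[paste(subj, st)]] <- e
  s <- summarize_errors(e)
  rows[[f]] <- data.frame(subject = subj, state = st, n = s$n,
                          mean_abs = s$mean_abs, sd_abs = s$sd_abs,
                          skewness_signed = s$skewness_signed,
                          mean_log_abs = mean(log_transform(abs(e))))
}
summary_tab <- do.call(rbind, rows)
write.table(summary_tab, "results/tables/error_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

subjects <- unique(summary_tab$subject)
order3 <- c("SWS", "AWAKE", "REM")
eff <- list()
for (subj in subjects) {
  for (a in 1:2) for (b in (a + 1):3) {
    ea <- errors[[paste(subj, order3[a])]]
    eb <- errors[[paste(subj, order3[b])]]
    es <- compare_states(log_transform(abs(ea)), log_transform(abs(eb)),
                         labels = order3[c(a, b)])
    eff[[paste(subj, a, b)]] <- data.frame(
      subject = subj, group_a = order3[a], group_b = order3[b],
      d = es$d, t = es$t_stat, df = es$df, p = es$p_value)
  }
}
eff_tab <- do.call(rbind, eff)
write.table(eff_tab, "results/tables/effect_sizes.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
# NOTE: p-values are reported uncorrected across the three state pairs.

spec_rows <- list()
for (f in list.files("results/data", pattern = "^s[0-9]+_(REM|AWAKE|SWS)\\.txt$")) {
  parts <- strsplit(sub("\\.txt$", "", f), "_")[[1]]
  tr <- read_text(file.path("results/data", f), fs = 100)
  sp <- power_spectrum(tr)
  spec_rows[[f]] <- data.frame(subject = parts[1], state = parts[2],
                               dominant_hz = sp$freqs[which.max(sp$power)],
                               alpha_fraction = alpha_band_power(sp))
}
spec_tab <- do.call(rbind, spec_rows)
write.table(spec_tab, "results/tables/spectra.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

message("Per-state mean |error| (samples), averaged over subjects:")
for (st in order3) {
  message(sprintf("  %-5s %.3f", st,
                  mean(summary_tab$mean_abs[summary_tab$state == st])))
}
ord_ok <- all(vapply(subjects, function(su) {
  m <- setNames(summary_tab$mean_log_abs[summary_tab$subject == su],
                summary_tab$state[summary_tab$subject == su])
  m[["REM"]] < m[["AWAKE"]] && m[["AWAKE"]] < m[["SWS"]]
}, logical(1)))
message("mean log|error| ordered REM < AWAKE < SWS in every subject: ", ord_ok)
message(sprintf("Cohen's d, SWS vs conscious states: %.2f-%.2f (all p < 1e-6: %s)",
                min(eff_tab$d[eff_tab$group_a == "SWS"]),
                max(eff_tab$d[eff_tab$group_a == "SWS"]),
                all(eff_tab$p[eff_tab$group_a == "SWS"] < 1e-6)))
message(sprintf("signed-error skewness: %.2f-%.2f (positive in %d/%d conditions)",
                min(summary_tab$skewness_signed), max(summary_tab$skewness_signed),
                sum(summary_tab$skewness_signed > 0), nrow(summary_tab)))
message(sprintf("SWS dominant frequency: %.2f-%.2f Hz; alpha fraction %.2f-%.2f",
                min(spec_tab$dominant_hz[spec_tab$state == "SWS"]),
                max(spec_tab$dominant_hz[spec_tab$state == "SWS"]),
                min(spec_tab$alpha_fraction[spec_tab$state == "SWS"]),
                max(spec_tab$alpha_fraction[spec_tab$state == "SWS"])))
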