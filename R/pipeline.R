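# End-to-end orchestration: load or generate traces, smooth, detect peaks,
# build interval series, train one network per (subject, state), evaluate on
# held-out pairs, and compare states.

derive_seed <- function(seed, index, offset = 0L) {
  as.integer((as.numeric(seed) + 7919 * index + 104729 * offset) %% 2147483647)
}

config_keys <- list(
  top = c("seed", "output_dir", "mode", "smoothing", "window", "training",
          "inputs"),
  smoothing = c("sigma", "truncation"),
  window = c("k", "normalize"),
  training = c("lambda0", "lambda_decrease", "lambda_increase", "max_epochs",
               "patience", "lambda_max"),
  input = c("subject", "state", "synthetic", "n_ipi", "path", "fs", "channel")
)

check_keys <- function(x, allowed, where, errors = character(0)) {
  unknown <- setdiff(names(x), allowed)
  for (u in unknown) {
    dist <- utils::adist(u, allowed, ignore.case = TRUE)
    hint <- if (min(dist) <= 3) paste0("; did you mean '", allowed[which.min(dist)], "'?") else ""
    errors <- c(errors, paste0("unknown key '", u, "' in ", where, hint))
  }
  errors
}

#' Validate and normalize a run configuration
#'
#' Accepts a YAML file path or an R list. Fills in the pipeline defaults
#' (k = 10, sigma = 1, lambda0 = 0.001, 60/15/25 chronological split), checks
#' every invariant, rejects unknown keys (with a spelling suggestion), and
#' either returns a fully resolved `run_config` or stops with all violations
#' listed at once.
#'
#' @param config Path to a YAML config file, or a named list with the same
#'   structure: `seed`, `output_dir`, optional `mode` ("IPI" or "RAW"),
#'   optional `smoothing`/`window`/`training` blocks, and `inputs` — a list of
#'   entries each naming a `subject`, a `state`, and either `synthetic` (a
#'   default profile name) plus `n_ipi`, or a `path` to a one-column text
#'   trace plus `fs`.
#' @return A `run_config` list with resolved sub-configurations.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  errors <- check_keys(config, config_keys$top, "config")
  errors <- check_keys(config$smoothing %||% list(), config_keys$smoothing,
                       "smoothing", errors)
  errors <- check_keys(config$window %||% list(), config_keys$window,
                       "window", errors)
  errors <- check_keys(config$training %||% list(), config_keys$training,
                       "training", errors)
  sm <- tryCatch(do.call(smoothing_config, config$smoothing %||% list()),
                 error = function(e) {errors <<- c(errors, paste0("smoothing_config: ", conditionMessage(e))); NULL})
  wc <- tryCatch(do.call(window_config, config$window %||% list()),
                 error = function(e) {errors <<- c(errors, paste0("window_config: ", conditionMessage(e))); NULL})
  tc <- tryCatch(do.call(training_config, config$training %||% list()),
                 error = function(e) {errors <<- c(errors, paste0("training_config: ", conditionMessage(e))); NULL})
  mode <- config$mode %||% "IPI"
  if (!mode %in% c("IPI", "RAW")) {
    errors <- c(errors, "mode must be 'IPI' or 'RAW'")
  }
  if (is.null(config$inputs) || length(config$inputs) == 0L) {
    errors <- c(errors, "config needs at least one entry under 'inputs'")
  }
  states <- character(0)
  for (i in seq_along(config$inputs)) {
    inp <- config$inputs[[i]]
    errors <- check_keys(inp, config_keys$input, paste0("inputs[", i, "]"), errors)
    if (is.null(inp$state) || !inp$state %in% c("AWAKE", "REM", "SWS")) {
      errors <- c(errors, paste0("inputs[", i, "]: state must be AWAKE, REM or SWS"))
    } else {
      states <- c(states, inp$state)
    }
    if (is.null(inp$synthetic) && is.null(inp$path)) {
      errors <- c(errors, paste0("inputs[", i, "]: needs either 'synthetic' or 'path'"))
    }
    if (!is.null(inp$synthetic) && !inp$synthetic %in% c("AWAKE", "REM", "SWS")) {
      errors <- c(errors, paste0("inputs[", i, "]: synthetic profile must be AWAKE, REM or SWS"))
    }
  }
  if (length(unique(states)) < 2L) {
    errors <- c(errors, "at least 2 distinct states are required for comparison")
  }
  if (length(errors)) {
    stop("invalid configuration:\n  - ", paste(errors, collapse = "\n  - "))
  }
  structure(list(seed = as.integer(config$seed %||% 1L),
                 output_dir = config$output_dir %||% NULL, mode = mode,
                 smoothing = sm, window = wc, training = tc,
                 inputs = config$inputs),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

load_input <- function(inp, config, index) {
  if (!is.null(inp$synthetic)) {
    profile <- default_profiles()[[inp$synthetic]]
    run <- simulate_run(profile, inp$n_ipi %||% 3000L,
                        seed = derive_seed(config$seed, index),
                        subject_id = inp$subject %||% "synthetic")
    run$trace$state <- inp$state
    run$trace
  } else {
    read_text(inp$path, fs = inp$fs %||% 100,
              channel = inp$channel %||% "unknown", state = inp$state,
              subject_id = inp$subject %||% basename(inp$path))
  }
}

#' Run the full analysis pipeline
#'
#' For every input: load or generate the trace, Gaussian-smooth it, detect
#' strict local maxima, form the interval series, window it with a 60/15/25
#' chronological split, train a fresh network (one per input, seeded
#' deterministically from the run seed), and evaluate on the held-out pairs.
#' Then, per subject, compare every state pair with a Welch t-test and pooled
#' Cohen's d on log-transformed absolute errors. Pairs are ordered so the
#' expected larger-error state comes first (SWS before AWAKE before REM):
#' positive d then means the first state is less predictable.
#'
#' In RAW mode the network predicts the smoothed continuous waveform directly
#' instead of intervals; the report stamps this mode exploratory, and no claim
#' is attached to it.
#'
#' Every stage logs counts (samples in, peaks found, pairs per split, epochs,
#' stopping reason); a failing input is recorded and the remaining inputs are
#' still processed. Given identical config and seed the result is
#' deterministic, including byte-identical report tables.
#'
#' @param config A `run_config` from [validate_config], a list, or a YAML path.
#' @param quiet Suppress per-stage log messages.
#' @return A `run_result`: list with `per_input` (per-input list of
#'   `ipi`, `dataset`, `model`, `errors`, `summary`), `summary_table`
#'   (data.frame), `effect_table` (data.frame), `failures`, `provenance`.
#'   If `config$output_dir` is set, report tables and model files are written
#'   there.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  say <- function(...) if (!quiet) message(sprintf(...))
  per <- list()
  failures <- list()
  for (i in seq_along(config$inputs)) {
    inp <- config$inputs[[i]]
    id <- paste0(inp$subject %||% "s", "/", inp$state)
    res <- tryCatch({
      trace <- load_input(inp, config, i)
      say("[%s] loaded %d samples @ %g Hz", id, length(trace$samples), trace$fs)
      smoothed <- gaussian_smooth(trace, config$smoothing)
      if (config$mode == "RAW") {
        y <- smoothed$samples
        k <- config$window$k
        n_pairs <- length(y) - k
        inputs <- matrix(0, n_pairs, k)
        for (j in seq_len(k)) inputs[, j] <- y[j:(j + n_pairs - 1L)]
        dataset <- windowed_dataset(inputs, y[(k + 1L):length(y)],
                                    normalize = config$window$normalize,
                                    unit_ms = 1000 / trace$fs)
        ipi <- NULL
        say("[%s] RAW mode: %d pairs from the continuous waveform", id, n_pairs)
      } else {
        peaks <- detect_peaks(smoothed)
        ipi <- compute_ipi(peaks, fs = trace$fs)
        say("[%s] %d peaks -> %d intervals (mean %.1f samples)", id,
            length(peaks$indices), length(ipi$intervals), mean(ipi$intervals))
        dataset <- split_series(ipi, config$window)
      }
      tb <- table(dataset$split)
      say("[%s] split: %d TRAIN / %d VAL / %d TEST", id,
          tb[["TRAIN"]], tb[["VAL"]], tb[["TEST"]])
      tconf <- config$training
      tconf$seed <- derive_seed(config$seed, i, offset = 1L)
      model <- train_lm(dataset, tconf)
      say("[%s] trained %d epochs (stop: %s), best val MSE %.4g", id,
          model$trace$epochs, model$trace$stop_reason, model$trace$best_val_mse)
      errors <- evaluate(model, dataset)
      list(subject = inp$subject %||% "s", state = inp$state, ipi = ipi,
           dataset = dataset, model = model, errors = errors,
           summary = summarize_errors(errors))
    }, error = function(e) {
      structure(list(input = id, message = conditionMessage(e)),
                class = "pipeline_failure")
    })
    if (inherits(res, "pipeline_failure")) {
      say("[%s] FAILED: %s", id, res$message)
      failures[[length(failures) + 1L]] <- res
    } else {
      per[[length(per) + 1L]] <- res
    }
  }
  if (!length(per)) stop("all inputs failed; first failure: ", failures[[1]]$message)

  summary_table <- do.call(rbind, lapply(per, function(r) {
    data.frame(subject = r$subject, state = r$state, n = r$summary$n,
               mean_abs = r$summary$mean_abs, sd_abs = r$summary$sd_abs,
               mean_signed = r$summary$mean_signed,
               skewness_signed = r$summary$skewness_signed,
               mean_log_abs = mean(log_transform(r$errors$abs_errors)),
               stringsAsFactors = FALSE)
  }))

  state_rank <- c(SWS = 1L, AWAKE = 2L, REM = 3L)
  effect_rows <- list()
  for (subj in unique(summary_table$subject)) {
    rs <- per[vapply(per, function(r) r$subject == subj, logical(1))]
    states <- vapply(rs, function(r) r$state, character(1))
    ord <- order(state_rank[states])
    rs <- rs[ord]; states <- states[ord]
    if (length(rs) < 2L) next
    for (a in seq_len(length(rs) - 1L)) {
      for (b in (a + 1L):length(rs)) {
        es <- compare_states(log_transform(rs[[a]]$errors$abs_errors),
                             log_transform(rs[[b]]$errors$abs_errors),
                             labels = c(states[a], states[b]))
        effect_rows[[length(effect_rows) + 1L]] <- data.frame(
          subject = subj, group_a = states[a], group_b = states[b],
          d = es$d, t_stat = es$t_stat, df = es$df, p_value = es$p_value,
          n_a = es$n[1], n_b = es$n[2], stringsAsFactors = FALSE)
      }
    }
  }
  effect_table <- if (length(effect_rows)) do.call(rbind, effect_rows) else NULL

  result <- structure(
    list(per_input = per, summary_table = summary_table,
         effect_table = effect_table, failures = failures,
         provenance = list(seed = config$seed, mode = config$mode,
                           package_version = as.character(utils::packageVersion("ipipredict")),
                           n_inputs = length(config$inputs))),
    class = "run_result")
  if (!is.null(config$output_dir)) write_report(result, config$output_dir)
  result
}

#' Write report tables and models for a pipeline result
#'
#' Emits `error_summary.tsv` (per-state summaries), `effect_sizes.tsv`
#' (pairwise Welch t and Cohen's d; no multiple-testing correction is applied
#' across the three state pairs, and the table header flags this), one model
#' JSON per input, and `provenance.json`. Numeric columns are printed with 10
#' significant digits so identical runs produce byte-identical files.
#'
#' @param result A `run_result`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(result, dir) {
  stopifnot(inherits(result, "run_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fmt <- function(df) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) formatC(x, format = "g", digits = 10))
    df
  }
  header <- "# per-state IPI prediction error summaries (sample units; 1 sample = 10 ms at 100 Hz)"
  if (result$provenance$mode == "RAW") {
    header <- c(header,
                "# mode=RAW: exploratory continuous-waveform prediction; no claims attached")
  }
  f1 <- file.path(dir, "error_summary.tsv")
  writeLines(header, f1)
  suppressWarnings(utils::write.table(fmt(result$summary_table), f1, sep = "\t",
                                      quote = FALSE, row.names = FALSE,
                                      append = TRUE))
  if (!is.null(result$effect_table)) {
    f2 <- file.path(dir, "effect_sizes.tsv")
    writeLines(c("# pairwise Welch t-test and pooled-SD Cohen's d on log|error|; d = group_a - group_b",
                 "# p-values are uncorrected for the multiple state pairs"), f2)
    suppressWarnings(utils::write.table(fmt(result$effect_table), f2, sep = "\t",
                                        quote = FALSE, row.names = FALSE,
                                        append = TRUE))
  }
  for (r in result$per_input) {
    write_model(r$model, file.path(dir, sprintf("model_%s_%s.json",
                                                r$subject, r$state)))
  }
  jsonlite::write_json(result$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @export
print.run_result <- function(x, ...) {
  cat(sprintf("<run_result> %d input(s), %d failure(s)\n",
              length(x$per_input), length(x$failures)))
  print(x$summary_table)
  if (!is.null(x$effect_table)) print(x$effect_table)
  invisible(x)
}
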