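#' Windowing configuration for one-step prediction
#'
#' @param k Window length: number of past intervals fed to the predictor
#'   (default 10).
#' @param normalize Z-score inputs and targets by training-set statistics
#'   (default `TRUE`). Raw IPI magnitudes (~10-15 samples) sit far outside the
#'   sensitive range of tanh hidden units, which makes the damped Gauss-Newton
#'   normal equations ill-conditioned; normalization is undone before errors
#'   are reported.
#' @return A `window_config` list.
#' @export
window_config <- function(k = 10, normalize = TRUE) {
  stopifnot(is.numeric(k), length(k) == 1L, k >= 1, k == round(k),
            is.logical(normalize), length(normalize) == 1L)
  structure(list(k = as.integer(k), normalize = normalize),
            class = "window_config")
}

#' Build a windowed dataset from explicit input/target pairs
#'
#' Pairs are tagged chronologically: the first 60% TRAIN, the next 15% VAL,
#' the remainder TEST (TRAIN and VAL counts rounded down, remainder to TEST).
#' Normalization statistics (a single mean and SD) are computed from TRAIN
#' inputs and targets only, then applied to all pairs.
#'
#' @param inputs Numeric matrix, one k-length window per row.
#' @param targets Numeric vector, the value following each window.
#' @param normalize Z-score by TRAIN statistics.
#' @param fractions Chronological split fractions for TRAIN and VAL.
#' @param unit_ms Milliseconds per sample carried along for reporting.
#' @return A `windowed_dataset`: list with normalized `inputs`, `targets`,
#'   `split` (factor TRAIN/VAL/TEST), `norm_stats` (`mean`, `sd`), `k`.
#' @export
windowed_dataset <- function(inputs, targets, normalize = TRUE,
                             fractions = c(train = 0.60, val = 0.15),
                             unit_ms = 10) {
  inputs <- as.matrix(inputs)
  targets <- as.numeric(targets)
  n <- nrow(inputs)
  stopifnot(n == length(targets), n >= 2L)
  # VAL (and in the extreme TEST) may be empty on very short series; training
  # enforces its own minimum split sizes
  n_train <- max(1L, floor(fractions[["train"]] * n))
  n_val <- floor(fractions[["val"]] * n)
  n_test <- n - n_train - n_val
  split <- factor(rep(c("TRAIN", "VAL", "TEST"), c(n_train, n_val, n_test)),
                  levels = c("TRAIN", "VAL", "TEST"))
  tr <- split == "TRAIN"
  if (normalize) {
    vals <- c(as.numeric(inputs[tr, , drop = FALSE]), targets[tr])
    m <- mean(vals)
    s <- stats::sd(vals)
    if (!is.finite(s) || s == 0) s <- 1  # constant series: shift only
  } else {
    m <- 0; s <- 1
  }
  structure(
    list(inputs = (inputs - m) / s, targets = (targets - m) / s,
         split = split, norm_stats = c(mean = m, sd = s),
         k = ncol(inputs), unit_ms = unit_ms),
    class = "windowed_dataset"
  )
}

#' @export
print.windowed_dataset <- function(x, ...) {
  tb <- table(x$split)
  cat(sprintf("<windowed_dataset> %d pairs (k = %d): %d TRAIN / %d VAL / %d TEST; norm mean %.3f sd %.3f\n",
              length(x$targets), x$k, tb[["TRAIN"]], tb[["VAL"]], tb[["TEST"]],
              x$norm_stats[["mean"]], x$norm_stats[["sd"]]))
  invisible(x)
}

#' Window an IPI series into one-step prediction pairs
#'
#' Traverses the interval series with a window of length `k`; each window of
#' consecutive values is an input vector and the value immediately following
#' it is the target, giving `length(series) - k` pairs. Pairs are then tagged
#' chronologically 60/15/25 into TRAIN/VAL/TEST (adjacent windows share k-1
#' values, so a shuffled split would leak test information into training;
#' chronological splitting avoids that).
#'
#' @param ipi An `ipi_series`.
#' @param config A [window_config].
#' @return A `windowed_dataset`.
#' @export
split_series <- function(ipi, config = window_config()) {
  stopifnot(inherits(ipi, "ipi_series"), inherits(config, "window_config"))
  y <- as.numeric(ipi$intervals)
  k <- config$k
  n_pairs <- length(y) - k
  if (n_pairs < 2L) {
    stop("series of ", length(y), " intervals is too short for k = ", k,
         "; need at least ", k + 2L, " intervals to form windowed pairs")
  }
  inputs <- matrix(0, n_pairs, k)
  for (j in seq_len(k)) inputs[, j] <- y[j:(j + n_pairs - 1L)]
  windowed_dataset(inputs, y[(k + 1L):length(y)], normalize = config$normalize,
                   unit_ms = ipi$unit_ms)
}

subset_pairs <- function(data, which) {
  sel <- data$split == which
  list(X = data$inputs[sel, , drop = FALSE], y = data$targets[sel])
}
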