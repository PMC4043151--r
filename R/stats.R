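#' Moment-based sample skewness
#'
#' The plain moment estimator `g1 = m3 / m2^(3/2)` with central moments
#' `m_r = mean((x - mean(x))^r)`, without small-sample bias correction (with
#' roughly 2000 errors per condition the correction is negligible).
#'
#' @param x Numeric vector, length >= 2, non-constant.
#' @return The sample skewness.
#' @export
skewness_g1 <- function(x) {
  stopifnot(length(x) >= 2L)
  d <- x - mean(x)
  m2 <- mean(d^2)
  if (m2 == 0) return(0)
  mean(d^3) / m2^1.5
}

#' Summarize a prediction-error record
#'
#' Mean and SD of absolute errors, skewness of signed errors, and a histogram
#' of signed errors on fixed unit-width bins in sample units.
#'
#' @param errors An `error_record` from [evaluate] (>= 2 errors), or a numeric
#'   vector of signed errors.
#' @return An `error_summary`: list with `n`, `mean_abs`, `sd_abs`,
#'   `mean_signed`, `skewness_signed`, `histogram` (`breaks`, `counts`).
#' @export
summarize_errors <- function(errors) {
  signed <- if (inherits(errors, "error_record")) errors$signed_errors else as.numeric(errors)
  n <- length(signed)
  if (n < 2L) stop("need at least 2 errors to summarize, got ", n)
  ab <- abs(signed)
  breaks <- seq(floor(min(signed)), ceiling(max(signed)) + 1) - 0.5
  h <- graphics::hist(signed, breaks = breaks, plot = FALSE)
  structure(list(n = n, mean_abs = mean(ab), sd_abs = stats::sd(ab),
                 mean_signed = mean(signed),
                 skewness_signed = skewness_g1(signed),
                 histogram = list(breaks = h$breaks, counts = h$counts)),
            class = "error_summary")
}

#' @export
print.error_summary <- function(x, ...) {
  cat(sprintf("<error_summary> n = %d: mean |e| = %.3f (SD %.3f), signed skewness %.3f\n",
              x$n, x$mean_abs, x$sd_abs, x$skewness_signed))
  invisible(x)
}

#' Log-transform absolute errors
#'
#' Natural log of `|e| + 1e-8`. Absolute prediction errors are strongly
#' positively skewed; the log transform makes them t-test friendly. The small
#' epsilon keeps the transform total on exact zeros (which have measure zero
#' for a continuous-output predictor).
#'
#' @param abs_errors Nonnegative numeric vector (absolute errors).
#' @return The transformed vector.
#' @export
log_transform <- function(abs_errors) {
  abs_errors <- as.numeric(abs_errors)
  if (any(abs_errors < 0)) {
    stop("log_transform expects nonnegative absolute errors; got a negative value")
  }
  log(abs_errors + 1e-8)
}

#' Compare two error populations: Welch t-test and Cohen's d
#'
#' Welch's two-sample t-test (unequal variances) on the supplied values
#' (typically log-transformed absolute errors), plus Cohen's d with the pooled
#' standard deviation `sqrt(((n_a-1) s_a^2 + (n_b-1) s_b^2) / (n_a+n_b-2))`.
#' Sign convention: first group minus second, so `d > 0` means group `a` has
#' the larger mean (larger error when comparing log absolute errors).
#'
#' @param a,b Numeric vectors (each n >= 2), e.g. from [log_transform].
#' @param labels Character pair naming the groups.
#' @return An `effect_size`: list with `d`, `t_stat`, `p_value`, `df`,
#'   `group_labels`, `n`.
#' @export
compare_states <- function(a, b, labels = c("a", "b")) {
  a <- as.numeric(a); b <- as.numeric(b)
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  sa <- stats::sd(a); sb <- stats::sd(b)
  if (sa == 0 && sb == 0) {
    if (mean(a) == mean(b)) {
      return(structure(list(d = 0, t_stat = 0, p_value = 1,
                            df = length(a) + length(b) - 2,
                            group_labels = labels,
                            n = c(length(a), length(b))),
                       class = "effect_size"))
    }
    stop("both groups have zero variance with different means; t-test undefined")
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  na <- length(a); nb <- length(b)
  pooled <- sqrt(((na - 1) * sa^2 + (nb - 1) * sb^2) / (na + nb - 2))
  structure(list(d = (mean(a) - mean(b)) / pooled,
                 t_stat = unname(tt$statistic), p_value = tt$p.value,
                 df = unname(tt$parameter), group_labels = labels,
                 n = c(na, nb)),
            class = "effect_size")
}

#' @export
print.effect_size <- function(x, ...) {
  cat(sprintf("<effect_size> %s vs %s: d = %.4f, Welch t = %.2f (df %.1f), p = %.3g\n",
              x$group_labels[1], x$group_labels[2], x$d, x$t_stat, x$df,
              x$p_value))
  invisible(x)
}
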