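#' Uniformly sampled single-channel signal trace
#'
#' The basic container carried through the pipeline: an ordered vector of
#' amplitudes (microvolts for EEG), the sampling rate, a channel label, a
#' sleep/wake state label and a subject identifier.
#'
#' @param samples Numeric vector of amplitudes; length >= 2, all finite.
#' @param fs Sampling rate in Hz (default 100, the rate of the Fpz-Cz
#'   recordings this pipeline targets).
#' @param channel Free-text channel label, e.g. "Fpz-Cz".
#' @param state One of `"AWAKE"`, `"REM"`, `"SWS"`, `"UNKNOWN"`.
#' @param subject_id Free-text subject identifier.
#'
#' @return An object of class `signal_trace`: a list with elements `samples`,
#'   `fs`, `channel`, `state`, `subject_id`.
#' @export
#' @examples
#' tr <- signal_trace(sin(2 * pi * 2 * (0:999) / 100), fs = 100)
#' tr
signal_trace <- function(samples, fs = 100, channel = "unknown",
                         state = c("UNKNOWN", "AWAKE", "REM", "SWS"),
                         subject_id = "unknown") {
  state <- match.arg(state)
  samples <- as.numeric(samples)
  if (length(samples) < 2L) {
    stop("a signal_trace needs at least 2 samples, got ", length(samples))
  }
  if (!all(is.finite(samples))) {
    bad <- which(!is.finite(samples))
    stop("signal contains ", length(bad), " non-finite sample(s), first at index ",
         bad[1L], "; clean the input before loading")
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("fs must be a single positive number (Hz)")
  }
  structure(
    list(samples = samples, fs = as.numeric(fs), channel = as.character(channel),
         state = state, subject_id = as.character(subject_id)),
    class = "signal_trace"
  )
}

#' @export
print.signal_trace <- function(x, ...) {
  cat(sprintf("<signal_trace> %d samples @ %g Hz (%.2f s), channel '%s', state %s, subject '%s'\n",
              length(x$samples), x$fs, length(x$samples) / x$fs,
              x$channel, x$state, x$subject_id))
  invisible(x)
}

#' @export
length.signal_trace <- function(x) length(x$samples)

#' Read a one-column text trace
#'
#' Parses a plain-text file with one numeric value per line. Blank lines and
#' lines starting with `#` are ignored. The sampling rate is not stored in the
#' file and must be supplied by the caller.
#'
#' @param path Path to the file.
#' @param fs Sampling rate in Hz.
#' @inheritParams signal_trace
#' @return A [signal_trace].
#' @export
read_text <- function(path, fs, channel = "unknown",
                      state = c("UNKNOWN", "AWAKE", "REM", "SWS"),
                      subject_id = "unknown") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  vals <- suppressWarnings(as.numeric(trimws(lines[keep])))
  if (anyNA(vals)) {
    bad <- idx[which(is.na(vals))[1L]]
    stop("non-numeric value at line ", bad, " of ", path, ": '", lines[bad], "'")
  }
  signal_trace(vals, fs = fs, channel = channel, state = state,
               subject_id = subject_id)
}

#' Write a trace as one-column text
#'
#' Values are printed with 12 significant digits so that
#' `read_text(write_text(x))` reproduces the values to printed precision.
#'
#' @param trace A [signal_trace].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_text <- function(trace, path) {
  stopifnot(inherits(trace, "signal_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# channel=%s state=%s subject=%s fs=%g",
                     trace$channel, trace$state, trace$subject_id, trace$fs), con)
  writeLines(formatC(trace$samples, format = "g", digits = 12), con)
  invisible(path)
}
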