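# Minimal European Data Format (EDF) I/O: 256-byte fixed-width ASCII header,
# 256 bytes of per-signal header fields, then data records of little-endian
# int16 samples scaled between the declared digital and physical ranges.

edf_field <- function(raw, from, len) {
  trimws(rawToChar(raw[from:(from + len - 1L)]))
}

read_edf_header <- function(path) {
  size <- file.info(path)$size
  if (is.na(size) || size < 256) stop("not a valid EDF file (header truncated): ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  h <- readBin(con, "raw", n = 256L)
  ns <- suppressWarnings(as.integer(edf_field(h, 253L, 4L)))
  n_rec <- suppressWarnings(as.integer(edf_field(h, 237L, 8L)))
  dur <- suppressWarnings(as.numeric(edf_field(h, 245L, 8L)))
  header_bytes <- suppressWarnings(as.integer(edf_field(h, 185L, 8L)))
  if (is.na(ns) || ns < 1L || is.na(header_bytes)) {
    stop("not a valid EDF file (malformed header): ", path)
  }
  if (size < 256 + 256 * ns) stop("not a valid EDF file (signal header truncated): ", path)
  sh <- readBin(con, "raw", n = 256L * ns)
  # per-signal fields are stored field-major: all labels, all transducers, ...
  offs <- c(label = 0L, transducer = 16L * ns, dim = 96L * ns, pmin = 104L * ns,
            pmax = 112L * ns, dmin = 120L * ns, dmax = 128L * ns,
            prefilter = 136L * ns, nsamp = 216L * ns)
  fld <- function(start, len) {
    vapply(seq_len(ns), function(i) {
      edf_field(sh, start + (i - 1L) * len + 1L, len)
    }, character(1))
  }
  list(
    ns = ns, n_records = n_rec, duration = dur, header_bytes = header_bytes,
    labels = fld(offs[["label"]], 16L),
    phys_dim = fld(offs[["dim"]], 8L),
    phys_min = as.numeric(fld(offs[["pmin"]], 8L)),
    phys_max = as.numeric(fld(offs[["pmax"]], 8L)),
    dig_min = as.numeric(fld(offs[["dmin"]], 8L)),
    dig_max = as.numeric(fld(offs[["dmax"]], 8L)),
    samples_per_record = as.integer(fld(offs[["nsamp"]], 8L))
  )
}

#' Read one channel from an EDF file
#'
#' Reads a single signal from a European Data Format file, scaling digital
#' int16 values to physical units using the header's digital/physical ranges.
#' The sampling rate is taken from the header (samples per record divided by
#' record duration).
#'
#' @param path Path to the EDF file.
#' @param channel Channel label to extract (must match a header label).
#' @inheritParams signal_trace
#' @return A [signal_trace] with `fs` from the EDF header.
#' @export
read_edf <- function(path, channel,
                     state = c("UNKNOWN", "AWAKE", "REM", "SWS"),
                     subject_id = "unknown") {
  if (!file.exists(path)) stop("file not found: ", path)
  hdr <- read_edf_header(path)
  i <- match(channel, hdr$labels)
  if (is.na(i)) {
    stop("channel '", channel, "' not found; available channels: ",
         paste(sprintf("'%s'", hdr$labels), collapse = ", "))
  }
  if (is.na(hdr$duration) || hdr$duration <= 0) {
    stop("EDF record duration is not positive; non-uniform or malformed sampling rejected")
  }
  rec_words <- sum(hdr$samples_per_record)
  n_rec <- hdr$n_records
  if (is.na(n_rec) || n_rec < 0L) {  # -1 means "unknown"; infer from file size
    n_rec <- (file.info(path)$size - hdr$header_bytes) %/% (2L * rec_words)
  }
  if (n_rec < 1L) stop("EDF file contains no data records: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", n = hdr$header_bytes))
  dig <- integer(0)
  before <- if (i > 1L) sum(hdr$samples_per_record[seq_len(i - 1L)]) else 0L
  after <- rec_words - before - hdr$samples_per_record[i]
  out <- vector("list", n_rec)
  for (r in seq_len(n_rec)) {
    if (before > 0L) invisible(readBin(con, "raw", n = 2L * before))
    out[[r]] <- readBin(con, "integer", n = hdr$samples_per_record[i],
                        size = 2L, signed = TRUE, endian = "little")
    if (after > 0L) invisible(readBin(con, "raw", n = 2L * after))
  }
  dig <- unlist(out)
  scale <- (hdr$phys_max[i] - hdr$phys_min[i]) / (hdr$dig_max[i] - hdr$dig_min[i])
  phys <- (dig - hdr$dig_min[i]) * scale + hdr$phys_min[i]
  fs <- hdr$samples_per_record[i] / hdr$duration
  signal_trace(phys, fs = fs, channel = channel, state = state,
               subject_id = subject_id)
}

#' Write traces to an EDF file
#'
#' Writes one or more equal-length traces as a single-record EDF file, mapping
#' each signal's physical range onto the full 16-bit digital range. Mainly used
#' to build round-trip fixtures and to export synthetic traces in the format
#' real recordings arrive in.
#'
#' @param traces A [signal_trace] or list of them, all of equal length and
#'   sampling rate.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(traces, path) {
  if (inherits(traces, "signal_trace")) traces <- list(traces)
  stopifnot(length(traces) >= 1L, all(vapply(traces, inherits, logical(1), "signal_trace")))
  n <- length(traces[[1L]]$samples)
  fs <- traces[[1L]]$fs
  if (!all(vapply(traces, function(t) length(t$samples) == n && t$fs == fs, logical(1)))) {
    stop("all traces must share length and sampling rate")
  }
  ns <- length(traces)
  pad <- function(x, w) formatC(substr(as.character(x), 1L, w), width = w, flag = "-")
  num <- function(x, w) {
    s <- formatC(x, format = "g", digits = 7, width = -1)
    if (nchar(s) > w) s <- substr(s, 1L, w)
    formatC(s, width = w, flag = "-")
  }
  pmin_ <- vapply(traces, function(t) min(t$samples), numeric(1))
  pmax_ <- vapply(traces, function(t) max(t$samples), numeric(1))
  flat <- pmax_ - pmin_ == 0
  pmin_[flat] <- pmin_[flat] - 1
  pmax_[flat] <- pmax_[flat] + 1
  dmin <- -32768; dmax <- 32767
  header <- paste0(
    pad("0", 8L), pad("X X X X", 80L), pad("Startdate X X X X", 80L),
    pad("01.01.00", 8L), pad("00.00.00", 8L),
    pad(256L + 256L * ns, 8L), pad("", 44L),
    pad("1", 8L), num(n / fs, 8L), pad(ns, 4L)
  )
  sig <- paste0(
    paste(vapply(traces, function(t) pad(t$channel, 16L), character(1)), collapse = ""),
    paste(rep(pad("", 80L), ns), collapse = ""),
    paste(rep(pad("uV", 8L), ns), collapse = ""),
    paste(vapply(pmin_, num, character(1), w = 8L), collapse = ""),
    paste(vapply(pmax_, num, character(1), w = 8L), collapse = ""),
    paste(rep(pad(dmin, 8L), ns), collapse = ""),
    paste(rep(pad(dmax, 8L), ns), collapse = ""),
    paste(rep(pad("", 80L), ns), collapse = ""),
    paste(rep(pad(n, 8L), ns), collapse = ""),
    paste(rep(pad("", 32L), ns), collapse = "")
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(header, sig)), con)
  for (t in seq_len(ns)) {
    scale <- (pmax_[t] - pmin_[t]) / (dmax - dmin)
    dig <- round((traces[[t]]$samples - pmin_[t]) / scale + dmin)
    dig <- as.integer(pmin(pmax(dig, dmin), dmax))
    writeBin(dig, con, size = 2L, endian = "little")
  }
  invisible(path)
}
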