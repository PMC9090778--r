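# Minimal EDF (European Data Format) reader/writer.
#
# EDF stores a 256-byte fixed header, one 256-byte header per signal, then
# 16-bit little-endian samples grouped into data records. We write a single
# data record spanning the whole segment, which keeps the format exact for
# arbitrary segment lengths (no zero-padded tail record). Physical scaling
# uses the standard (physical min/max, digital min/max) affine map, so a
# round-trip is exact up to the 16-bit quantization step.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) stop_spindlr("EDF header field too wide: ", x)
  formatC(x, width = width, flag = "-")
}

edf_num <- function(x, width) {
  s <- formatC(x, format = "fg", width = 1, digits = 7)
  s <- substr(s, 1, width)
  edf_pad(s, width)
}

#' Write signals to an EDF file
#'
#' @param path Output file path.
#' @param signals A named list of numeric vectors (microvolts), one per
#'   channel. All channels must share the sampling rate but may differ in
#'   length (shorter channels are zero-padded to the longest).
#' @param fs Sampling rate in Hz.
#' @return `path`, invisibly.
#' @export
write_edf <- function(path, signals, fs) {
  if (is.numeric(signals)) signals <- list(EEG = signals)
  if (is.null(names(signals)) || any(!nzchar(names(signals))))
    stop_spindlr("`signals` must be a named list of channels")
  check_scalar_num(fs, "fs", lower = 1e-9)
  ns <- length(signals)
  n <- max(vapply(signals, length, 1L))
  signals <- lapply(signals, function(x) c(x, rep(0, n - length(x))))

  dmin <- -32768; dmax <- 32767
  pmin <- vapply(signals, function(x) min(min(x), -1e-6), 1)
  pmax <- vapply(signals, function(x) max(max(x), 1e-6), 1)

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad("X X X X", 80),
    edf_pad("Startdate X X X X", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (1 + ns), 8),
    edf_pad("", 44),
    edf_pad(1, 8),                     # one data record
    edf_num(n / fs, 8),                # record duration [s]
    edf_pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  field <- function(f, width) for (i in seq_len(ns)) writeChar(f(i, width), con, eos = NULL)
  field(function(i, w) edf_pad(names(signals)[i], w), 16)
  field(function(i, w) edf_pad("", w), 80)                 # transducer
  field(function(i, w) edf_pad("uV", w), 8)
  field(function(i, w) edf_num(pmin[i], w), 8)
  field(function(i, w) edf_num(pmax[i], w), 8)
  field(function(i, w) edf_pad(dmin, w), 8)
  field(function(i, w) edf_pad(dmax, w), 8)
  field(function(i, w) edf_pad("", w), 80)                 # prefiltering
  field(function(i, w) edf_pad(n, w), 8)
  field(function(i, w) edf_pad("", w), 32)
  for (i in seq_len(ns)) {
    # physical -> digital
    x <- signals[[i]]
    dig <- round((x - pmin[i]) / (pmax[i] - pmin[i]) * (dmax - dmin) + dmin)
    writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read one channel from an EDF file
#'
#' @param path EDF file path.
#' @param channel Channel label to extract; `NULL` (default) takes the first
#'   channel.
#' @return A list with `samples` (numeric, physical units), `fs` (Hz) and
#'   `channel` (the label actually read).
#' @export
read_edf <- function(path, channel = NULL) {
  if (!file.exists(path)) stop_spindlr("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width, n = 1) {
    raw <- readChar(con, width * n, useBytes = TRUE)
    if (is.na(raw) || nchar(raw, type = "bytes") < width * n)
      stop_spindlr("EDF format error: truncated header in ", path)
    trimws(substring(raw, seq(1, width * n, by = width),
                     seq(width, width * n, by = width)))
  }
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                # header bytes
  rd(44)
  n_rec <- suppressWarnings(as.integer(rd(8)))
  rec_dur <- suppressWarnings(as.numeric(rd(8)))
  ns <- suppressWarnings(as.integer(rd(4)))
  if (is.na(n_rec) || is.na(rec_dur) || is.na(ns) || ns < 1)
    stop_spindlr("EDF format error: unreadable header in ", path)
  labels <- rd(16, ns); rd(80, ns); rd(8, ns)
  pmin <- as.numeric(rd(8, ns)); pmax <- as.numeric(rd(8, ns))
  dmin <- as.numeric(rd(8, ns)); dmax <- as.numeric(rd(8, ns))
  rd(80, ns)
  spr <- as.integer(rd(8, ns))
  rd(32, ns)

  idx <- if (is.null(channel)) 1L else match(channel, labels)
  if (is.na(idx))
    stop_spindlr("channel '", channel, "' not found; available: ",
                 paste(labels, collapse = ", "))
  out <- numeric(0)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[i], size = 2, endian = "little")
      if (length(dig) < spr[i])
        stop_spindlr("EDF format error: truncated data in ", path)
      if (i == idx)
        out <- c(out, (dig - dmin[i]) / (dmax[i] - dmin[i]) *
                   (pmax[i] - pmin[i]) + pmin[i])
    }
  }
  fs <- spr[idx] / rec_dur
  # the record duration is stored as ASCII with 8 characters; snap rates
  # that are integral to within the resulting quantization error
  if (abs(fs - round(fs)) < 0.01) fs <- round(fs)
  list(samples = out, fs = fs, channel = labels[idx])
}
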