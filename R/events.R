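# Spindle annotations are plain data frames with columns `onset` and
# `duration`, both in seconds from segment start; intervals are half-open
# [onset, onset + duration). The on-disk interchange format is CSV with
# header `onset_s,duration_s` at 1 ms precision, mirrored by a JSON variant.

#' Construct a spindle event list
#'
#' @param onset Numeric vector of event onsets (seconds from segment start).
#' @param duration Numeric vector of event durations (seconds), all `> 0`.
#' @return A data frame with columns `onset` and `duration`, sorted by onset.
#'   Overlapping events trigger a warning but are kept as-is (reference
#'   annotations are never edited silently).
#' @export
event_list <- function(onset = numeric(0), duration = numeric(0)) {
  if (length(onset) != length(duration))
    stop_spindlr("onset and duration must have equal length")
  if (length(onset) && (any(!is.finite(onset)) || any(!is.finite(duration))))
    stop_spindlr("events must be finite")
  if (any(duration <= 0))
    stop_spindlr("event durations must be > 0")
  ord <- order(onset)
  ev <- data.frame(onset = as.numeric(onset[ord]),
                   duration = as.numeric(duration[ord]))
  if (nrow(ev) > 1 &&
      any(ev$onset[-1] < (ev$onset + ev$duration)[-nrow(ev)]))
    warning("event list contains overlapping events; kept as-is")
  ev
}

#' Read spindle annotations (CSV or JSON)
#'
#' CSV files must carry columns `onset_s` and `duration_s`; JSON files an
#' array of objects with those keys (or a single object of two arrays).
#'
#' @param path File path; format inferred from the `.json` extension,
#'   CSV otherwise.
#' @return An [event_list()] data frame sorted by onset.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop_spindlr("no such file: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    x <- jsonlite::fromJSON(path)
    if (length(x) == 0) return(event_list())
    return(event_list(x$onset_s, x$duration_s))
  }
  x <- utils::read.csv(path)
  if (nrow(x) == 0) return(event_list())
  if (!all(c("onset_s", "duration_s") %in% names(x)))
    stop_spindlr("annotation CSV must have columns onset_s,duration_s")
  event_list(x$onset_s, x$duration_s)
}

#' Write spindle annotations (CSV or JSON)
#'
#' Values are written at 1 ms precision.
#'
#' @param events An [event_list()] data frame.
#' @param path Output path; `.json` selects the JSON mirror format.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(events, path) {
  out <- data.frame(onset_s = round(events$onset, 3),
                    duration_s = round(events$duration, 3))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(out, path, digits = NA)
  } else {
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

# Rasterize events onto the sample grid: sample i (0-based, time i/fs) is 1
# iff i/fs lies in some [onset, onset + duration).
#' Convert an event list to a per-sample 0/1 indicator
#'
#' @param events An [event_list()] data frame.
#' @param n Number of samples in the segment.
#' @param fs Sampling rate (Hz).
#' @return Integer vector of length `n` with 1 inside events.
#' @export
events_to_indicator <- function(events, n, fs) {
  ind <- integer(n)
  for (j in seq_len(nrow(events))) {
    i0 <- ceiling(events$onset[j] * fs - 1e-9)
    i1 <- ceiling((events$onset[j] + events$duration[j]) * fs - 1e-9) - 1
    i0 <- max(i0, 0); i1 <- min(i1, n - 1)
    if (i1 >= i0) ind[(i0 + 1):(i1 + 1)] <- 1L
  }
  ind
}
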