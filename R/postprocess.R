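# Converts raw probability tracks into spindle annotations: centered
# moving-average smoothing, pointwise class decision, and joining of
# consecutive positive samples into events.

#' Smooth a probability track with a centered moving average
#'
#' Both channels are convolved with a uniform kernel of odd width; edges
#' are handled by symmetric reflection (the edge sample is included in the
#' mirror), so constant channels are preserved exactly and the channel sum
#' remains 1 at every sample.
#'
#' @param track A `probability_track` (see [predict_track()]).
#' @param width Kernel width in samples; odd, `>= 1`, at most the track
#'   length.
#' @return The smoothed `probability_track`.
#' @export
smooth_track <- function(track, width) {
  n <- length(track$spindle)
  if (width < 1 || width %% 2 == 0)
    stop_spindlr("`width` must be an odd integer >= 1")
  if (width > n)
    stop_spindlr("smoothing width (", width, ") exceeds track length (", n, ")")
  track$spindle <- moving_average(track$spindle, width)
  track$no_spindle <- moving_average(track$no_spindle, width)
  track
}

# Uniform moving average with symmetric-reflection padding.
moving_average <- function(x, width) {
  if (width == 1) return(x)
  p <- (width - 1) %/% 2
  n <- length(x)
  xp <- c(x[p:1], x, x[n:(n - p + 1)])
  as.numeric(stats::filter(xp, rep(1 / width, width), sides = 2))[(p + 1):(p + n)]
}

#' Pointwise class decision
#'
#' Sample `i` is marked as spindle iff the spindle probability strictly
#' exceeds the no-spindle probability (under the sum-to-1 invariant this is
#' the 0.5-threshold rule); exact ties resolve to no-spindle.
#'
#' @param track A `probability_track`.
#' @return Integer 0/1 vector.
#' @export
to_indicator <- function(track) {
  as.integer(track$spindle > track$no_spindle)
}

#' Join consecutive positive indicator samples into events
#'
#' Maximal runs of 1s become events with `onset = first_index / fs` (0-based
#' indexing) and `duration = run_length / fs`, i.e. the half-open sample
#' convention.
#'
#' @param indicator Integer/logical 0/1 vector.
#' @param fs Sampling rate (Hz).
#' @return An [event_list()] data frame.
#' @export
indicator_to_events <- function(indicator, fs) {
  r <- rle(as.integer(indicator) > 0)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  if (!any(keep)) return(event_list())
  event_list(onset = (starts[keep] - 1) / fs,
             duration = r$lengths[keep] / fs)
}

#' Predict spindle annotations for a segment
#'
#' The full inference chain: [predict_track()] (raw probabilities),
#' [smooth_track()] with the configured moving-average width (nominal
#' seconds, rounded to the nearest odd sample count), [to_indicator()], and
#' [indicator_to_events()]. Optionally drops events shorter than
#' `min_duration` (off by default: no minimum-duration rule is part of the
#' detector itself).
#'
#' @param net A trained network.
#' @param segment Z-scored 100 Hz samples (vector), or a T x B matrix.
#' @param min_duration Minimum event duration in seconds (0 disables).
#' @return An [event_list()], or a list of them for matrix input.
#' @export
predict_events <- function(net, segment, min_duration = 0) {
  cfg <- net$config
  width <- round(cfg$moving_avg_s * cfg$fs)
  if (width %% 2 == 0) width <- width + 1
  tracks <- predict_track(net, segment)
  single <- inherits(tracks, "probability_track")
  if (single) tracks <- list(tracks)
  out <- lapply(tracks, function(tr) {
    ev <- indicator_to_events(to_indicator(smooth_track(tr, width)), cfg$fs)
    if (min_duration > 0) ev <- ev[ev$duration >= min_duration, , drop = FALSE]
    ev
  })
  if (single) out[[1]] else out
}
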