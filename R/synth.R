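# Synthetic N2-sleep EEG with planted, ground-truth-annotated sigma bursts.
#
# The generator emulates the study conditions of the consensus-annotated
# corpus the detector targets: artifact-free 115 s N2 segments at 100 Hz,
# spindles as 11-16 Hz bursts of >= 0.5 s, per-subject spindle densities
# drawn from a bimodal distribution with modes near 1 and 5.25 per minute,
# and an older cohort with reduced spindle amplitude and duration.

#' Synthetic EEG generator configuration
#'
#' @param fs Sampling rate (Hz).
#' @param segment_s Segment length (seconds).
#' @param alpha Background spectral exponent: background power spectral
#'   density falls off as `1/f^alpha`.
#' @param freq_range Spindle oscillation frequency range (Hz), drawn
#'   uniformly per event.
#' @param dur_range Spindle duration range (seconds), drawn uniformly per
#'   event; the lower edge enforces the 0.5 s scoring minimum.
#' @param density_modes Modes of the per-subject spindle density mixture
#'   (events per minute).
#' @param density_sds Normal spread around each mode (events per minute).
#' @param density_weights Mixture weights of the two modes.
#' @param snr Amplitude of planted bursts, expressed as the ratio of the
#'   burst's sigma-band (11-16 Hz) RMS over the event window to the
#'   background's sigma-band RMS.
#' @param distractor_rate Rate (per minute) of non-spindle slow-wave
#'   transients (0.5-2 Hz bumps) added to the background.
#' @param min_gap Minimum separation between planted events (seconds).
#' @param older_amp_factor,older_dur_factor Multipliers applied to burst
#'   amplitude and duration for the older cohort (durations are clamped to
#'   stay `>= dur_range[1]`).
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(fs = 100, segment_s = 115, alpha = 1,
                         freq_range = c(11, 16), dur_range = c(0.5, 1.5),
                         density_modes = c(1, 5.25),
                         density_sds = c(0.25, 1),
                         density_weights = c(0.5, 0.5),
                         snr = 2, distractor_rate = 0, min_gap = 0.5,
                         older_amp_factor = 0.7, older_dur_factor = 0.85) {
  stopifnot(fs > 0, segment_s > 0, dur_range[1] >= 0.5,
            freq_range[1] >= 11, freq_range[2] <= 16)
  structure(list(fs = fs, segment_s = segment_s, alpha = alpha,
                 freq_range = freq_range, dur_range = dur_range,
                 density_modes = density_modes, density_sds = density_sds,
                 density_weights = density_weights, snr = snr,
                 distractor_rate = distractor_rate, min_gap = min_gap,
                 older_amp_factor = older_amp_factor,
                 older_dur_factor = older_dur_factor),
            class = "synth_config")
}

#' Generate 1/f colored-noise background
#'
#' Shapes white Gaussian noise in the Fourier domain so the power spectral
#' density falls off as `1/f^alpha`, then rescales to unit standard
#' deviation. Optional slow-wave distractors (0.5-2 Hz Hann-windowed bumps)
#' are superimposed at `config$distractor_rate` per minute.
#'
#' @param config A [synth_config()].
#' @param n_samples Number of samples to generate.
#' @param seed Optional seed; the ambient RNG is used when `NULL`.
#' @return Numeric vector of length `n_samples` (unit-SD background).
#' @export
generate_background <- function(config, n_samples, seed = NULL) {
  with_seed(seed, {
    n <- n_samples
    w <- stats::rnorm(n)
    X <- stats::fft(w)
    f <- c(1e-12, seq_len(n - 1)) * config$fs / n   # guard DC
    f <- pmin(f, config$fs - f)                     # two-sided frequency axis
    shape <- 1 / f^(config$alpha / 2)
    shape[1] <- 0                                   # kill DC
    x <- Re(stats::fft(X * shape, inverse = TRUE)) / n
    x <- x / stats::sd(x)
    n_dis <- stats::rpois(1, config$distractor_rate * n / config$fs / 60)
    for (i in seq_len(n_dis)) {
      f0 <- stats::runif(1, 0.5, 2)
      dur <- stats::runif(1, 0.8, 1.5)
      len <- round(dur * config$fs)
      at <- sample.int(max(n - len, 1), 1)
      tt <- (seq_len(len) - 1) / config$fs
      bump <- 2 * hann_window(len) * sin(2 * pi * f0 * tt)
      idx <- at:(at + len - 1)
      x[idx] <- x[idx] + bump[seq_along(idx)]
    }
    x
  })
}

hann_window <- function(n) {
  if (n == 1) return(1)
  0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
}

# Sigma-band (11-16 Hz) RMS of a signal, zero-phase 4th-order Butterworth.
sigma_band_rms <- function(x, fs, band = c(11, 16)) {
  filt <- signal::butter(2, band / (fs / 2), type = "pass")
  pad <- min(3 * 60, length(x) - 1)
  left <- 2 * x[1] - x[(pad + 1):2]
  right <- 2 * x[length(x)] - x[(length(x) - 1):(length(x) - pad)]
  y <- signal::filter(filt, c(left, x, right))
  y <- rev(signal::filter(filt, rev(y)))
  sqrt(mean(y[(pad + 1):(pad + length(x))]^2))
}

#' Plant a sigma-band burst into a segment
#'
#' Adds a Hann-windowed sinusoid over `[onset, onset + duration)`. The
#' `amplitude` argument is the target RMS of the burst over its own window
#' (for mid-band frequencies and durations ~1 s essentially all of that
#' energy lies in the 11-16 Hz band); the peak amplitude of the underlying
#' sinusoid is scaled accordingly.
#'
#' @param samples Numeric segment to modify.
#' @param fs Sampling rate (Hz).
#' @param onset Event onset (seconds).
#' @param duration Event duration (seconds).
#' @param freq Oscillation frequency (Hz).
#' @param amplitude Target in-window RMS of the added burst.
#' @param phase Oscillation phase offset (radians).
#' @return A list with the modified `samples` and the ground-truth `event`
#'   (one-row [event_list()]).
#' @export
plant_spindle <- function(samples, fs, onset, duration, freq, amplitude,
                          phase = 0) {
  n <- length(samples)
  i0 <- round(onset * fs) + 1
  len <- round(duration * fs)
  if (i0 < 1 || i0 + len - 1 > n)
    stop_spindlr("event [", onset, ", ", onset + duration,
                 ") does not fit inside the segment")
  tt <- (seq_len(len) - 1) / fs
  w <- hann_window(len)
  burst <- w * sin(2 * pi * freq * tt + phase)
  rms0 <- sqrt(mean(burst^2))
  if (rms0 > 0 && amplitude > 0) burst <- burst * (amplitude / rms0)
  else burst <- burst * 0
  samples[i0:(i0 + len - 1)] <- samples[i0:(i0 + len - 1)] + burst
  list(samples = samples,
       event = event_list(onset = onset, duration = duration))
}

# Draw one subject-level spindle density (events/minute) from the bimodal
# mixture; truncated at 0.2/min so every subject expresses some spindles.
draw_density <- function(config) {
  k <- sample.int(2, 1, prob = config$density_weights)
  max(stats::rnorm(1, config$density_modes[k], config$density_sds[k]), 0.2)
}

# Place n_events onsets in [margin, span - margin - dur] with pairwise
# separation >= min_gap; bounded rejection sampling.
place_events <- function(n_events, durations, span, min_gap, tries = 1000) {
  if (n_events == 0) return(numeric(0))
  margin <- 0.25
  for (t in seq_len(tries)) {
    onsets <- stats::runif(n_events, margin, span - margin - durations)
    ord <- order(onsets)
    o <- onsets[ord]; d <- durations[ord]
    if (n_events == 1 || all(o[-1] - (o + d)[-n_events] >= min_gap))
      return(list(onset = o, duration = d))
    if (t == tries)
      stop_spindlr("could not place ", n_events,
                   " events with the required separation")
  }
}

#' Generate all segments of one synthetic subject
#'
#' The subject's spindle density is drawn once from the bimodal mixture;
#' each segment then receives a Poisson number of events at that density,
#' placed uniformly with at least `config$min_gap` separation. For the
#' older cohort, burst amplitude and duration are scaled down
#' (`older_amp_factor`, `older_dur_factor`) to emulate the age-related
#' attenuation of spindles; durations never drop below the 0.5 s minimum.
#'
#' @param config A [synth_config()].
#' @param n_segments Number of segments (3 or 10 in the emulated corpus).
#' @param subject_id Subject identifier string.
#' @param cohort `"younger"` or `"older"`.
#' @param seed Optional seed.
#' @return A list with `segments` (list of numeric vectors), `annotations`
#'   (list of [event_list()]s), `density` (the drawn density), and subject
#'   metadata.
#' @export
generate_subject <- function(config, n_segments = 3,
                             subject_id = "s01", cohort = "younger",
                             seed = NULL) {
  cohort <- match.arg(cohort, c("younger", "older"))
  with_seed(seed, {
    density <- draw_density(config)
    amp_f <- if (cohort == "older") config$older_amp_factor else 1
    dur_f <- if (cohort == "older") config$older_dur_factor else 1
    n <- round(config$segment_s * config$fs)
    segments <- vector("list", n_segments)
    annotations <- vector("list", n_segments)
    for (s in seq_len(n_segments)) {
      bg <- generate_background(config, n)
      amp <- config$snr * amp_f * sigma_band_rms(bg, config$fs)
      n_ev <- stats::rpois(1, density * config$segment_s / 60)
      durs <- pmax(stats::runif(n_ev, config$dur_range[1],
                                config$dur_range[2]) * dur_f,
                   config$dur_range[1])
      placed <- place_events(n_ev, durs, config$segment_s, config$min_gap)
      x <- bg
      if (n_ev > 0) {
        for (j in seq_len(n_ev)) {
          freq <- stats::runif(1, config$freq_range[1], config$freq_range[2])
          ph <- stats::runif(1, 0, 2 * pi)
          x <- plant_spindle(x, config$fs, placed$onset[j],
                             placed$duration[j], freq, amp, ph)$samples
        }
        annotations[[s]] <- event_list(placed$onset, placed$duration)
      } else {
        annotations[[s]] <- event_list()
      }
      segments[[s]] <- x
    }
    list(subject_id = subject_id, cohort = cohort, density = density,
         segments = segments, annotations = annotations)
  })
}

#' Generate a synthetic two-cohort dataset
#'
#' Mirrors the layout of the emulated corpus: `n_younger + n_older`
#' subjects, of which `n_ten` (split evenly across cohorts) contribute ten
#' segments and the rest three. When `out_dir` is given, signals are written
#' as EDF, annotations as CSV, and a YAML manifest ties them together;
#' otherwise everything stays in memory.
#'
#' @param config A [synth_config()].
#' @param n_younger,n_older Subjects per cohort.
#' @param n_ten Total number of ten-segment subjects (even, split equally
#'   across cohorts).
#' @param seed Seed for the whole dataset (per-subject seeds are derived
#'   from it).
#' @param out_dir Optional output directory for EDF/CSV/manifest files.
#' @return A list with `manifest` (data frame: subject_id, cohort,
#'   segment_id, and file paths when written), `segments` and `annotations`
#'   (named by segment_id), `densities` (per subject), and `config`.
#' @export
generate_dataset <- function(config, n_younger, n_older, n_ten = 0,
                             seed = 1, out_dir = NULL) {
  stopifnot(n_younger >= 0, n_older >= 0, n_ten %% 2 == 0,
            n_ten / 2 <= n_younger, n_ten / 2 <= n_older)
  cohorts <- c(rep("younger", n_younger), rep("older", n_older))
  n_seg <- c(rep(10, n_ten / 2), rep(3, n_younger - n_ten / 2),
             rep(10, n_ten / 2), rep(3, n_older - n_ten / 2))
  ids <- sprintf("s%03d", seq_along(cohorts))
  segments <- list(); annotations <- list()
  rows <- list(); densities <- numeric(length(ids))
  for (i in seq_along(ids)) {
    sub <- generate_subject(config, n_segments = n_seg[i],
                            subject_id = ids[i], cohort = cohorts[i],
                            seed = (seed * 1000L + i) %% .Machine$integer.max)
    densities[i] <- sub$density
    seg_ids <- sprintf("%s_seg%02d", ids[i], seq_len(n_seg[i]))
    names(sub$segments) <- seg_ids
    names(sub$annotations) <- seg_ids
    segments <- c(segments, sub$segments)
    annotations <- c(annotations, sub$annotations)
    rows[[i]] <- data.frame(subject_id = ids[i], cohort = cohorts[i],
                            segment_id = seg_ids)
  }
  manifest <- do.call(rbind, rows)
  names(densities) <- ids
  out <- list(manifest = manifest, segments = segments,
              annotations = annotations, densities = densities,
              config = config)
  if (!is.null(out_dir)) out <- write_dataset(out, out_dir)
  out
}

#' Write a generated dataset to disk (EDF + CSV + YAML manifest)
#'
#' @param dataset A dataset as returned by [generate_dataset()].
#' @param out_dir Output directory (created if missing).
#' @return The dataset, with `segment_path`/`annotation_path` columns added
#'   to its manifest.
#' @export
write_dataset <- function(dataset, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  m <- dataset$manifest
  m$segment_path <- file.path(out_dir, paste0(m$segment_id, ".edf"))
  m$annotation_path <- file.path(out_dir, paste0(m$segment_id, ".csv"))
  for (i in seq_len(nrow(m))) {
    sid <- m$segment_id[i]
    write_edf(m$segment_path[i], list(C3 = dataset$segments[[sid]]),
              fs = dataset$config$fs)
    write_annotations(dataset$annotations[[sid]], m$annotation_path[i])
  }
  dataset$manifest <- m
  recs <- lapply(unique(m$subject_id), function(sid) {
    d <- m[m$subject_id == sid, ]
    list(subject_id = sid, cohort = d$cohort[1],
         segment_paths = as.list(d$segment_path),
         annotation_paths = as.list(d$annotation_path))
  })
  yaml::write_yaml(list(sampling_rate = dataset$config$fs, records = recs),
                   file.path(out_dir, "manifest.yaml"))
  dataset
}

#' Read a dataset manifest written by [write_dataset()]
#'
#' @param path Path to a `manifest.yaml`.
#' @return A list with `manifest` (data frame) and `sampling_rate`.
#' @export
read_manifest <- function(path) {
  y <- yaml::read_yaml(path)
  rows <- lapply(y$records, function(r) {
    data.frame(subject_id = r$subject_id, cohort = r$cohort,
               segment_path = unlist(r$segment_paths),
               annotation_path = unlist(r$annotation_paths))
  })
  m <- do.call(rbind, rows)
  m$segment_id <- sub("\\.edf$", "", basename(m$segment_path))
  list(manifest = m, sampling_rate = y$sampling_rate)
}
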