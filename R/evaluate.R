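# Event-level evaluation against a reference annotation set: overlap-based
# one-to-one matching, recall/precision/F1, the F1 curve over overlap
# thresholds and its normalized integral (F1-bar), by-subject density and
# duration statistics, and the detector-scored test-split selection.

#' Relative overlap of two events
#'
#' Intersection length divided by the joined duration (length of the union)
#' of the two events; 1 for identical events, 0 for disjoint ones.
#'
#' @param a,b Events as `c(onset, duration)` in seconds.
#' @return Fraction in `[0, 1]`.
#' @export
relative_overlap <- function(a, b) {
  if (a[2] <= 0 || b[2] <= 0)
    stop_spindlr("events must have positive duration")
  inter <- max(0, min(a[1] + a[2], b[1] + b[2]) - max(a[1], b[1]))
  union <- a[2] + b[2] - inter
  min(inter / union, 1)      # guard rounding: the ratio is at most 1
}

# All pairwise relative overlaps between two event lists (matrix det x ref).
overlap_matrix <- function(detected, reference) {
  nd <- nrow(detected); nr <- nrow(reference)
  if (nd == 0 || nr == 0) return(matrix(0, nd, nr))
  d_on <- detected$onset; d_off <- detected$onset + detected$duration
  r_on <- reference$onset; r_off <- reference$onset + reference$duration
  inter <- pmax(0, outer(d_off, r_off, pmin) - outer(d_on, r_on, pmax))
  union <- outer(detected$duration, reference$duration, "+") - inter
  pmin(inter / union, 1)     # guard rounding: the ratio is at most 1
}

#' Match detected events to reference events
#'
#' Greedy one-to-one matching by descending relative overlap: the highest-
#' overlap unmatched pair is accepted while its overlap strictly exceeds
#' `threshold`. Matched pairs are true positives; unmatched reference events
#' are false negatives and unmatched detections false positives.
#'
#' @param detected,reference [event_list()] data frames from one segment.
#' @param threshold Overlap threshold in `(0, 1]`; strict (`>`) comparison,
#'   so `threshold = 0` accepts any positive overlap.
#' @return A list with integer `tp`, `fp`, `fn` and the `threshold`.
#' @export
match_events <- function(detected, reference, threshold = 0.2) {
  nd <- nrow(detected); nr <- nrow(reference)
  ov <- overlap_matrix(detected, reference)
  tp <- 0L
  if (nd > 0 && nr > 0) {
    repeat {
      best <- which.max(ov)
      if (length(best) == 0 || ov[best] <= threshold) break
      i <- (best - 1) %% nd + 1
      j <- (best - 1) %/% nd + 1
      tp <- tp + 1L
      ov[i, ] <- -1
      ov[, j] <- -1
    }
  }
  list(tp = tp, fp = nd - tp, fn = nr - tp, threshold = threshold)
}

#' Recall, precision and F1 from match counts
#'
#' `recall = TP/(TP+FN)`, `precision = TP/(TP+FP)`,
#' `F1 = 2 TP/(2 TP + FP + FN)`. Empty denominators follow the
#' perfect-empty convention: with no reference events, recall is 1 iff
#' there are also no detections (else 0); symmetrically for precision; the
#' all-empty case scores 1 throughout.
#'
#' @param counts A list with `tp`, `fp`, `fn` (see [match_events()]).
#' @return A list with `recall`, `precision`, `f1`.
#' @export
event_prf <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  recall <- if (tp + fn == 0) as.numeric(fp == 0) else tp / (tp + fn)
  precision <- if (tp + fp == 0) as.numeric(fn == 0) else tp / (tp + fp)
  f1 <- if (2 * tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn)
  list(recall = recall, precision = precision, f1 = f1)
}

#' F1 over a grid of overlap thresholds, and its normalized integral
#'
#' Computes match counts and F1 at each threshold of the grid and the
#' trapezoidal integral of the F1 curve divided by the grid span (F1-bar),
#' so a constant curve integrates to its value. With lists of event lists,
#' counts are pooled across segments before computing F1 (micro-averaging).
#'
#' @param detected,reference [event_list()]s, or lists of them (paired by
#'   position).
#' @param grid Sorted vector of overlap thresholds in `(0, 1]`; at least 2
#'   values for the integral.
#' @return A list with `curve` (data frame threshold/recall/precision/f1)
#'   and `f1_bar`.
#' @export
f1_curve <- function(detected, reference, grid = seq(0.05, 1, by = 0.05)) {
  if (length(grid) < 2) stop_spindlr("threshold grid needs >= 2 points")
  if (is.unsorted(grid) || any(grid <= 0) || any(grid > 1))
    stop_spindlr("grid must be sorted and within (0, 1]")
  if (is.data.frame(detected)) detected <- list(detected)
  if (is.data.frame(reference)) reference <- list(reference)
  if (length(detected) != length(reference))
    stop_spindlr("detected and reference lists must pair by position")
  rows <- lapply(grid, function(th) {
    tp <- fp <- fn <- 0L
    for (s in seq_along(detected)) {
      m <- match_events(detected[[s]], reference[[s]], th)
      tp <- tp + m$tp; fp <- fp + m$fp; fn <- fn + m$fn
    }
    pr <- event_prf(list(tp = tp, fp = fp, fn = fn))
    data.frame(threshold = th, recall = pr$recall,
               precision = pr$precision, f1 = pr$f1)
  })
  curve <- do.call(rbind, rows)
  span <- grid[length(grid)] - grid[1]
  f1_bar <- sum(diff(grid) * (utils::head(curve$f1, -1) +
                                utils::tail(curve$f1, -1)) / 2) / span
  list(curve = curve, f1_bar = f1_bar)
}

#' Per-subject spindle density and mean duration
#'
#' Events are pooled over all of the subject's segments: density is the
#' total event count divided by the total recorded minutes, mean duration
#' the arithmetic mean over all pooled events.
#'
#' @param events_by_segment List of [event_list()]s, one per segment.
#' @param total_minutes Total recorded time across those segments (min).
#' @return A list with `density` (events/min), `mean_duration` (s; `NA`
#'   with a `no_events` flag when the subject has no events) and `n_events`.
#' @export
subject_summary <- function(events_by_segment, total_minutes) {
  if (total_minutes <= 0) stop_spindlr("total_minutes must be > 0")
  if (is.data.frame(events_by_segment))
    events_by_segment <- list(events_by_segment)
  durs <- unlist(lapply(events_by_segment, function(e) e$duration))
  n <- length(durs)
  list(density = n / total_minutes,
       mean_duration = if (n > 0) mean(durs) else NA_real_,
       no_events = n == 0, n_events = n)
}

#' Compare predicted and reference subject-level characteristics
#'
#' Pearson correlation, ordinary least-squares fit of predicted on
#' reference values, and Fisher's z-transform of r.
#'
#' @param pred,ref Numeric vectors paired by subject, `n >= 4`.
#' @return A list with `r`, `r2`, `slope`, `intercept`, `fisher_z`, `n`.
#' @export
compare_summaries <- function(pred, ref) {
  if (length(pred) != length(ref) || length(pred) < 4)
    stop_spindlr("need >= 4 paired values")
  if (stats::sd(pred) == 0 || stats::sd(ref) == 0)
    stop_spindlr("zero variance: correlation undefined")
  r <- stats::cor(pred, ref)
  slope <- stats::cov(pred, ref) / stats::var(ref)
  list(r = r, r2 = r^2, slope = slope,
       intercept = mean(pred) - slope * mean(ref),
       fisher_z = atanh(r), n = length(pred))
}

#' Two-sample test of correlation difference via Fisher's z
#'
#' @param r1,r2 Correlations to compare.
#' @param n1,n2 Sample sizes behind them (each `> 3`).
#' @return A list with `z` (difference statistic) and two-sided `p`.
#' @export
fisher_z_test <- function(r1, n1, r2, n2) {
  if (n1 <= 3 || n2 <= 3) stop_spindlr("need n > 3 in both samples")
  se <- sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  z <- (atanh(r1) - atanh(r2)) / se
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Select a test split on which a reference detector performs at its median
#'
#' Draws `n_candidates` random by-subject splits subject to: ten-segment
#' subjects always train; the test set holds `n_test_per_cohort` subjects
#' from each cohort. Each candidate test set is scored by running
#' `detector` on its segments and computing the pooled F1 at the 20%
#' overlap threshold against the reference annotations; the candidate with
#' the median score is returned (for an even number of candidates, the
#' lower median).
#'
#' @param dataset A dataset from [generate_dataset()] (or the same shape).
#' @param detector Function `(samples, fs) -> event_list` applied per
#'   segment.
#' @param n_candidates Number of random candidates to draw.
#' @param n_test_per_cohort Test subjects per cohort.
#' @param seed Seed making the draw deterministic.
#' @return A list with `train_subjects`, `test_subjects`, `score` (the
#'   median candidate's F1\@20%), and `scores` of all candidates.
#' @export
select_test_split <- function(dataset, detector, n_candidates = 25,
                              n_test_per_cohort = 18, seed = 1) {
  m <- dataset$manifest
  seg_counts <- table(m$subject_id)
  subjects <- unique(m[c("subject_id", "cohort")])
  eligible <- subjects[seg_counts[subjects$subject_id] < 10, ]
  for (coh in c("younger", "older")) {
    if (sum(eligible$cohort == coh) < n_test_per_cohort)
      stop_spindlr("not enough eligible ", coh,
                   " subjects for the requested test size")
  }
  with_seed(seed, {
    candidates <- lapply(seq_len(n_candidates), function(i) {
      c(sample(eligible$subject_id[eligible$cohort == "younger"],
               n_test_per_cohort),
        sample(eligible$subject_id[eligible$cohort == "older"],
               n_test_per_cohort))
    })
    scores <- vapply(candidates, function(test_ids) {
      segs <- m$segment_id[m$subject_id %in% test_ids]
      det <- lapply(segs, function(sid)
        detector(dataset$segments[[sid]], dataset$config$fs))
      ref <- dataset$annotations[segs]
      th <- 0.2
      tp <- fp <- fn <- 0L
      for (s in seq_along(segs)) {
        mm <- match_events(det[[s]], ref[[s]], th)
        tp <- tp + mm$tp; fp <- fp + mm$fp; fn <- fn + mm$fn
      }
      event_prf(list(tp = tp, fp = fp, fn = fn))$f1
    }, 1)
    pick <- order(scores)[ceiling(n_candidates / 2)]
    test_ids <- candidates[[pick]]
    list(train_subjects = setdiff(subjects$subject_id, test_ids),
         test_subjects = test_ids,
         score = scores[pick], scores = scores)
  })
}

#' Simple sigma-power baseline detector
#'
#' A feature-based stand-in reference detector: band-pass to the sigma band,
#' moving RMS envelope, thresholding at `rel_threshold` times the segment's
#' median envelope, run-joining, and removal of runs shorter than 0.5 s
#' (the scoring minimum).
#'
#' @param samples Preprocessed (z-scored, 100 Hz) segment.
#' @param fs Sampling rate (Hz).
#' @param band Sigma band (Hz).
#' @param rel_threshold Envelope threshold relative to the segment median.
#' @param rms_window RMS window length (seconds).
#' @return An [event_list()].
#' @export
sigma_baseline_detector <- function(samples, fs, band = c(11, 16),
                                    rel_threshold = 1.8, rms_window = 0.3) {
  filt <- signal::butter(2, band / (fs / 2), type = "pass")
  n <- length(samples)
  pad <- min(120, n - 1)
  left <- 2 * samples[1] - samples[(pad + 1):2]
  right <- 2 * samples[n] - samples[(n - 1):(n - pad)]
  y <- signal::filter(filt, c(left, samples, right))
  y <- rev(signal::filter(filt, rev(y)))[(pad + 1):(pad + n)]
  w <- round(rms_window * fs)
  if (w %% 2 == 0) w <- w + 1
  env <- sqrt(moving_average(y^2, w))
  thr <- rel_threshold * stats::median(env)
  ev <- indicator_to_events(as.integer(env > thr), fs)
  ev[ev$duration >= 0.5, , drop = FALSE]
}
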