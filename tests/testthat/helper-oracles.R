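# Shared oracles and fixture builders. All fixtures are generated in code;
# oracles are deliberately independent of the implementation paths they
# check (brute-force enumeration, direct formula substitution, spectral
# evaluation of filter designs).

# Exhaustive optimal one-to-one matching: maximum number of (detected,
# reference) pairs with relative overlap strictly above `threshold`.
brute_force_tp <- function(detected, reference, threshold) {
  nd <- nrow(detected); nr <- nrow(reference)
  if (nd == 0 || nr == 0) return(0L)
  ov <- outer(seq_len(nd), seq_len(nr), Vectorize(function(i, j) {
    relative_overlap(c(detected$onset[i], detected$duration[i]),
                     c(reference$onset[j], reference$duration[j]))
  }))
  rec <- function(j, used) {
    if (j > nr) return(0L)
    best <- rec(j + 1L, used)
    for (i in seq_len(nd)) {
      if (!used[i] && ov[i, j] > threshold) {
        used[i] <- TRUE
        best <- max(best, 1L + rec(j + 1L, used))
        used[i] <- FALSE
      }
    }
    best
  }
  rec(1L, rep(FALSE, nd))
}

# Random non-overlapping event list on a ~`span`-second segment.
random_events <- function(n, span = 30) {
  if (n == 0) return(event_list())
  durs <- stats::runif(n, 0.3, 1.5)
  gaps <- stats::runif(n, 0.05, span / n)
  onsets <- cumsum(gaps) + c(0, cumsum(durs[-n]))
  event_list(onsets, durs)
}

# Squared magnitude response of a digital filter (b, a) at frequency f:
# the oracle for the forward-backward Butterworth band-pass.
filter_mag2 <- function(filt, f, fs) {
  z <- exp(-1i * 2 * pi * f / fs)
  bb <- sum(filt$b * z^(seq_along(filt$b) - 1))
  aa <- sum(filt$a * z^(seq_along(filt$a) - 1))
  Mod(bb / aa)^2
}

# Amplitude of the `f`-Hz component of x (least squares on sin/cos),
# estimated over the central half to avoid filter edge effects.
sine_amplitude <- function(x, f, fs) {
  n <- length(x)
  mid <- seq(round(n / 4), round(3 * n / 4))
  tt <- (mid - 1) / fs
  fit <- stats::lm(x[mid] ~ sin(2 * pi * f * tt) + cos(2 * pi * f * tt))
  sqrt(sum(stats::coef(fit)[2:3]^2))
}

# A tiny network whose head is pinned so the spindle probability is a
# constant below 0.5 regardless of input.
constant_no_spindle_net <- function() {
  net <- build_model(model_config(levels = 2, filters = c(4, 8),
                                  pools = c(4)), seed = 1)
  net$params$head$W[] <- 0
  net$params$head$b <- c(-2, 2)
  net
}

# Cheap fingerprint of a numeric vector, used to memoize per-segment
# detector output when scoring many candidate splits.
digest_key <- function(x) {
  sprintf("k%.12e_%.12e_%d", sum(x), x[1], length(x))
}

# Micro-averaged F1 at a 20% overlap threshold over paired event lists.
f1_at_20 <- function(det, ref) {
  tp <- fp <- fn <- 0L
  for (i in seq_along(det)) {
    m <- match_events(det[[i]], ref[[i]], 0.2)
    tp <- tp + m$tp; fp <- fp + m$fp; fn <- fn + m$fn
  }
  event_prf(list(tp = tp, fp = fp, fn = fn))$f1
}
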