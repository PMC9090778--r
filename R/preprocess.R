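# MODA-compatible signal conditioning. The order of operations is fixed:
# band-pass (zero-phase Butterworth, 0.3-30 Hz, effective 10th order) on the
# native-rate signal, downsample to 100 Hz, then z-transform each segment.

#' Zero-phase Butterworth band-pass filter
#'
#' A Butterworth band-pass of prototype order `order/2` is applied forward
#' and backward (`filtfilt` style), so the phase response is zero and the
#' magnitude response is the square of the design, i.e. an effective
#' `order`-th order roll-off. The signal is extended by odd reflection at
#' both ends before filtering so start-up transients decay inside the
#' padding; the pad length is `max(3 * order, fs / low)` samples, at least
#' one period of the lowest passband frequency.
#'
#' @param samples Numeric vector (microvolts or arbitrary units).
#' @param fs Sampling rate in Hz; must exceed `2 * high`.
#' @param low,high Passband corner frequencies in Hz.
#' @param order Effective filter order (even); the underlying design has
#'   prototype order `order / 2`.
#' @return Filtered vector of the same length.
#' @export
bandpass <- function(samples, fs, low = 0.3, high = 30, order = 10) {
  check_scalar_num(fs, "fs", 1e-9)
  if (fs <= 2 * high)
    stop_spindlr("fs must exceed twice the upper passband edge (fs > ",
                 2 * high, " Hz)")
  if (order %% 2 != 0) stop_spindlr("`order` must be even")
  pad <- max(3L * order, ceiling(fs / low))
  n <- length(samples)
  if (n <= pad + 1)
    stop_spindlr("input too short for filter warm-up (need > ", pad + 1,
                 " samples at fs = ", fs, " Hz)")
  filt <- signal::butter(order / 2, c(low, high) / (fs / 2), type = "pass")
  # the sample mean lies in the stopband: removing it up front is exact for
  # constants and eliminates the slowly decaying DC start-up transient
  samples <- samples - mean(samples)
  # odd reflection: anti-symmetric continuation about the end values
  left <- 2 * samples[1] - samples[(pad + 1):2]
  right <- 2 * samples[n] - samples[(n - 1):(n - pad)]
  x <- c(left, samples, right)
  y <- signal::filter(filt, x)
  y <- rev(signal::filter(filt, rev(y)))
  y[(pad + 1):(pad + n)]
}

#' Downsample by Fourier resampling
#'
#' Resamples to `fs_out` by truncating the discrete Fourier spectrum, which
#' is exact for signals already band-limited below the output Nyquist rate
#' (guaranteed here by the 30 Hz low-pass of [bandpass()]). Upsampling is
#' not supported.
#'
#' @param samples Numeric vector.
#' @param fs_in Input sampling rate (Hz).
#' @param fs_out Output sampling rate (Hz), `<= fs_in`.
#' @return Vector of length `round(length(samples) * fs_out / fs_in)`.
#' @export
resample_to <- function(samples, fs_in, fs_out = 100) {
  check_scalar_num(fs_in, "fs_in", 1e-9)
  check_scalar_num(fs_out, "fs_out", 1e-9)
  if (fs_in < fs_out)
    stop_spindlr("no upsampling path: fs_in (", fs_in,
                 ") < fs_out (", fs_out, ")")
  if (fs_in == fs_out) return(samples)
  n <- length(samples)
  m <- round(n * fs_out / fs_in)
  X <- stats::fft(samples)
  Y <- complex(m)
  keep <- floor(m / 2)               # positive-frequency bins to retain
  Y[1] <- X[1]
  if (keep >= 1) {
    Y[2:(keep + 1)] <- X[2:(keep + 1)]
    Y[m - (1:keep) + 1] <- X[n - (1:keep) + 1]
  }
  if (m %% 2 == 0) {
    # shared Nyquist bin: fold the symmetric pair to keep the output real
    Y[keep + 1] <- X[keep + 1] + X[n - keep + 1]
  }
  Re(stats::fft(Y, inverse = TRUE)) / n
}

#' Per-segment z-transform
#'
#' Centers to zero mean and scales to unit variance using the population
#' convention (divisor `N`).
#'
#' @param samples Numeric vector of length at least 2, not constant.
#' @return Standardized vector: mean 0, population standard deviation 1.
#' @export
zscore <- function(samples) {
  if (length(samples) < 2) stop_spindlr("zscore needs at least 2 samples")
  if (any(!is.finite(samples))) stop_spindlr("non-finite samples")
  mu <- mean(samples)
  sd_pop <- sqrt(mean((samples - mu)^2))
  if (sd_pop == 0)
    stop_spindlr("constant segment: z-transform undefined")
  (samples - mu) / sd_pop
}

#' Full signal conditioning chain
#'
#' Applies, in this order: [bandpass()] at the native rate, [resample_to()]
#' down to `fs_out`, and [zscore()]. This order matters: z-scoring before
#' resampling would normalize against out-of-band energy that the band-pass
#' subsequently removes.
#'
#' @param samples Raw EEG samples (microvolts).
#' @param fs Native sampling rate (Hz).
#' @param fs_out Target rate (default 100 Hz).
#' @param low,high,order Band-pass parameters, see [bandpass()].
#' @return A list with `samples` (z-scored, at `fs_out`) and `fs`.
#' @export
preprocess_segment <- function(samples, fs, fs_out = 100,
                               low = 0.3, high = 30, order = 10) {
  x <- bandpass(samples, fs, low = low, high = high, order = order)
  x <- resample_to(x, fs, fs_out)
  list(samples = zscore(x), fs = fs_out)
}
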