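# The slim 1D U-Net: a branching encoder (two composite Conv-ReLU-BN
# layers per level, then max-pooling) down to a bottleneck, mirrored by a
# decoder (nearest-neighbor upsampling + a width-w conv mapping to half the
# channels, concatenation of the matching encoder activations through the
# shortcut, then two composite layers), and a width-1 conv head with a
# softmax over the two classes (spindle / no-spindle). All convolutions
# are length-preserving ("same" zero padding), so the output probability
# track has one (spindle, no-spindle) pair per input sample.

#' U-Net model configuration
#'
#' "Levels" counts pooled encoder levels plus the bottleneck: the default
#' 3-level model has two max-pooling steps of widths `pools = c(w1, w2)`.
#' Every composite convolution has effective extent `(kernel - 1) * dilation`
#' samples; the default `kernel = 9, dilation = 1` (extent 8) is the unique
#' calibration under which the third-level receptive field comes out at
#' 1.48 s / 3.52 s / 6.24 s for `w2 = 1 / 4 / 8` at 100 Hz.
#'
#' @param levels Encoder depth including the bottleneck.
#' @param filters Channels per level; must double level-to-level.
#' @param kernel,dilation Composite-convolution kernel size and dilation.
#' @param pools Max-pooling widths, one per non-bottleneck level
#'   (`length(pools) == levels - 1`).
#' @param moving_avg_s Width (seconds) of the moving-average filter applied
#'   to the raw probability track before thresholding; the sample count is
#'   forced odd so smoothing is centered.
#' @param threshold Decision threshold on the smoothed spindle probability.
#' @param fs Sampling rate the model operates at (Hz).
#' @return A list of class `model_config`.
#' @export
model_config <- function(levels = 3, filters = c(16, 32, 64),
                         kernel = 9, dilation = 1, pools = c(4, 4),
                         moving_avg_s = 0.42, threshold = 0.5, fs = 100) {
  if (length(filters) != levels)
    stop_spindlr("`filters` must have one entry per level (", levels, ")")
  if (levels > 1 && any(filters[-1] != 2 * filters[-levels]))
    stop_spindlr("`filters` must double from each level to the next")
  if (length(pools) != levels - 1)
    stop_spindlr("`pools` must have length levels - 1")
  if (any(pools < 1)) stop_spindlr("pool widths must be >= 1")
  if (kernel < 1 || dilation < 1)
    stop_spindlr("kernel and dilation must be >= 1")
  structure(list(levels = levels, filters = filters, kernel = kernel,
                 dilation = dilation, pools = pools,
                 moving_avg_s = moving_avg_s, threshold = threshold,
                 fs = fs),
            class = "model_config")
}

#' Receptive field of a bottleneck-level neuron
#'
#' Closed-form accounting: starting from 1 sample, each composite
#' convolution adds `(kernel - 1) * dilation` times the cumulative stride,
#' and each max-pooling adds `(width - 1)` times the pre-pool stride while
#' multiplying the stride by its width. With two convolutions per level this
#' is affine in the last pool width.
#'
#' @param config A [model_config()].
#' @param units `"samples"` or `"seconds"` (at `config$fs`).
#' @return The receptive field in the requested units.
#' @export
receptive_field <- function(config, units = c("samples", "seconds")) {
  units <- match.arg(units)
  rf <- 1
  stride <- 1
  ext <- (config$kernel - 1) * config$dilation
  for (i in seq_len(config$levels)) {
    rf <- rf + 2 * ext * stride            # two composite convs per level
    if (i < config$levels) {
      rf <- rf + (config$pools[i] - 1) * stride
      stride <- stride * config$pools[i]
    }
  }
  if (units == "seconds") rf / config$fs else rf
}

new_conv <- function(c_in, c_out, k, d = 1) {
  list(W = matrix(0, c_out, k * c_in), b = numeric(c_out),
       k = k, d = d, c_in = c_in, c_out = c_out)
}

new_bn <- function(c) list(gamma = rep(1, c), beta = rep(0, c))

#' Build the U-Net
#'
#' Constructs all parameter tensors for the configured architecture and
#' initializes convolution weights with Kaiming-uniform initialization
#' (see [init_params()]).
#'
#' @param config A [model_config()].
#' @param seed Seed for the weight initialization.
#' @return A network object (list with `config`, `params`, `bufs`).
#' @export
build_model <- function(config, seed = NULL) {
  L <- config$levels
  f <- config$filters
  k <- config$kernel; d <- config$dilation
  params <- list()
  c_prev <- 1
  for (i in seq_len(L)) {
    params[[paste0("e", i, "c1")]] <- new_conv(c_prev, f[i], k, d)
    params[[paste0("e", i, "b1")]] <- new_bn(f[i])
    params[[paste0("e", i, "c2")]] <- new_conv(f[i], f[i], k, d)
    params[[paste0("e", i, "b2")]] <- new_bn(f[i])
    c_prev <- f[i]
  }
  for (i in rev(seq_len(L - 1))) {
    w <- config$pools[i]
    params[[paste0("d", i, "up")]] <- new_conv(f[i + 1], f[i + 1] %/% 2, w, 1)
    params[[paste0("d", i, "c1")]] <- new_conv(f[i] + f[i + 1] %/% 2, f[i], k, d)
    params[[paste0("d", i, "b1")]] <- new_bn(f[i])
    params[[paste0("d", i, "c2")]] <- new_conv(f[i], f[i], k, d)
    params[[paste0("d", i, "b2")]] <- new_bn(f[i])
  }
  params[["head"]] <- new_conv(f[1], 2, 1, 1)
  bufs <- list()
  for (nm in names(params)) {
    if (!is.null(params[[nm]]$gamma)) {
      c <- length(params[[nm]]$gamma)
      bufs[[nm]] <- list(mean = numeric(c), var = rep(1, c))
    }
  }
  net <- list(config = config, params = params, bufs = bufs)
  init_params(net, seed)
}

#' (Re-)initialize network parameters
#'
#' Convolution weights are drawn from the Kaiming-uniform distribution
#' `U(-b, b)` with `b = sqrt(6 / fan_in)` (ReLU gain), `fan_in = kernel *
#' in_channels`; biases from `U(-1/sqrt(fan_in), 1/sqrt(fan_in))`. Batch
#' norm starts at identity (`gamma = 1, beta = 0`) with reset running
#' statistics.
#'
#' @param net A network from [build_model()].
#' @param seed Seed; the same seed reproduces identical parameters.
#' @return The initialized network.
#' @export
init_params <- function(net, seed = NULL) {
  with_seed(seed, {
    for (nm in names(net$params)) {
      p <- net$params[[nm]]
      if (!is.null(p$W)) {
        fan_in <- p$k * p$c_in
        bound <- sqrt(6 / fan_in)
        p$W[] <- stats::runif(length(p$W), -bound, bound)
        p$b[] <- stats::runif(length(p$b), -1 / sqrt(fan_in), 1 / sqrt(fan_in))
        net$params[[nm]] <- p
      } else {
        net$params[[nm]]$gamma[] <- 1
        net$params[[nm]]$beta[] <- 0
        net$bufs[[nm]] <- list(mean = numeric(length(p$gamma)),
                               var = rep(1, length(p$gamma)))
      }
    }
    net
  })
}

#' Number of trainable parameters
#'
#' @param net A network from [build_model()].
#' @return Total count of trainable scalars (conv weights and biases, batch
#'   norm scales and shifts).
#' @export
count_params <- function(net) {
  sum(vapply(net$params, function(p) {
    length(p[["W"]]) + length(p[["b"]]) +
      length(p[["gamma"]]) + length(p[["beta"]])
  }, 1))
}

# Full forward pass. X: (1, T, B) array, T already padded to a multiple of
# prod(pools). Returns probabilities (2, T, B) and, if keep_cache, all
# intermediate activations needed by net_backward.
net_forward <- function(net, X, training = FALSE, keep_cache = FALSE) {
  cfg <- net$config
  L <- cfg$levels
  cache <- if (keep_cache) list() else NULL
  skips <- vector("list", L - 1)
  x <- X

  block <- function(x, cname, bname) {
    cin <- x
    y <- conv_fwd(x, net$params[[cname]])
    a <- relu_fwd(y)
    bn <- bn_fwd(a, net$params[[bname]], net$bufs[[bname]], training)
    net$bufs[[bname]] <<- bn$buf
    if (keep_cache)
      cache[[cname]] <<- list(conv_in = cin, relu_out = a, bn = bn$cache)
    bn$Y
  }

  for (i in seq_len(L - 1)) {
    x <- block(x, paste0("e", i, "c1"), paste0("e", i, "b1"))
    x <- block(x, paste0("e", i, "c2"), paste0("e", i, "b2"))
    skips[[i]] <- x
    mp <- maxpool_fwd(x, cfg$pools[i])
    if (keep_cache) cache[[paste0("pool", i)]] <- mp$arg
    x <- mp$Y
  }
  x <- block(x, paste0("e", L, "c1"), paste0("e", L, "b1"))
  x <- block(x, paste0("e", L, "c2"), paste0("e", L, "b2"))

  for (i in rev(seq_len(L - 1))) {
    w <- cfg$pools[i]
    up_in <- upsample_fwd(x, w)
    upname <- paste0("d", i, "up")
    upc <- conv_fwd(up_in, net$params[[upname]])
    if (keep_cache) cache[[upname]] <- list(conv_in = up_in)
    x <- concat_fwd(skips[[i]], upc)
    x <- block(x, paste0("d", i, "c1"), paste0("d", i, "b1"))
    x <- block(x, paste0("d", i, "c2"), paste0("d", i, "b2"))
  }
  z <- conv_fwd(x, net$params[["head"]])
  if (keep_cache) cache[["head"]] <- list(conv_in = x)
  P <- softmax2_fwd(z)
  if (keep_cache) cache[["softmax_P"]] <- P
  list(P = P, cache = cache, bufs = net$bufs)
}

# Backward pass from dP (gradient of the loss w.r.t. the softmax output).
# Returns a named list of parameter gradients with slots matching the
# parameter slots (W, b, gamma, beta).
net_backward <- function(net, cache, dP) {
  cfg <- net$config
  L <- cfg$levels
  grads <- list()

  block_bwd <- function(dy, cname, bname) {
    cc <- cache[[cname]]
    bb <- bn_bwd(dy, cc$bn, net$params[[bname]])
    grads[[bname]] <<- list(gamma = bb$dgamma, beta = bb$dbeta)
    da <- relu_bwd(bb$dX, cc$relu_out)
    cb <- conv_bwd(da, cc$conv_in, net$params[[cname]])
    grads[[cname]] <<- list(W = cb$dW, b = cb$db)
    cb$dX
  }

  dz <- softmax2_bwd(dP, cache[["softmax_P"]])
  hb <- conv_bwd(dz, cache[["head"]]$conv_in, net$params[["head"]])
  grads[["head"]] <- list(W = hb$dW, b = hb$db)
  dx <- hb$dX

  dskips <- vector("list", L - 1)
  for (i in seq_len(L - 1)) {
    dx <- block_bwd(dx, paste0("d", i, "c2"), paste0("d", i, "b2"))
    dx <- block_bwd(dx, paste0("d", i, "c1"), paste0("d", i, "b1"))
    sp <- concat_bwd(dx, dim(dx)[1] - net$params[[paste0("d", i, "up")]]$c_out)
    dskips[[i]] <- sp$dA
    upname <- paste0("d", i, "up")
    ub <- conv_bwd(sp$dB, cache[[upname]]$conv_in, net$params[[upname]])
    grads[[upname]] <- list(W = ub$dW, b = ub$db)
    dx <- upsample_bwd(ub$dX, cfg$pools[i])
  }

  dx <- block_bwd(dx, paste0("e", L, "c2"), paste0("e", L, "b2"))
  dx <- block_bwd(dx, paste0("e", L, "c1"), paste0("e", L, "b1"))

  for (i in rev(seq_len(L - 1))) {
    dx <- maxpool_bwd(dx, cache[[paste0("pool", i)]], cfg$pools[i])
    dx <- dx + dskips[[i]]
    dx <- block_bwd(dx, paste0("e", i, "c2"), paste0("e", i, "b2"))
    dx <- block_bwd(dx, paste0("e", i, "c1"), paste0("e", i, "b1"))
  }
  grads
}

# Right-pad a T x B sample matrix with zeros so T is a multiple of the
# pooling product; returns the (1, Tp, B) array and the original length.
pad_batch <- function(xmat, pools) {
  if (is.null(dim(xmat))) xmat <- matrix(xmat, ncol = 1)
  Tt <- nrow(xmat); B <- ncol(xmat)
  P <- prod(pools)
  Tp <- as.integer(ceiling(Tt / P) * P)
  if (Tp > Tt) xmat <- rbind(xmat, matrix(0, Tp - Tt, B))
  array(as.numeric(xmat), c(1, Tp, B))
}

#' Forward pass: per-sample spindle probabilities
#'
#' Runs the network in inference mode (batch norm uses running statistics)
#' on one or more z-scored 100 Hz segments. Segments whose length is not a
#' multiple of the pooling product are right-padded with zeros internally
#' and the output is cropped back, so the track always has exactly one
#' probability pair per input sample.
#'
#' @param net A network from [build_model()] (typically trained).
#' @param segment Numeric vector of z-scored samples, or a T x B matrix of
#'   equal-length segments in columns.
#' @return For a vector input, a `probability_track`: list with `spindle`
#'   and `no_spindle` (each length T, summing to 1 pointwise) and `fs`.
#'   For a matrix input, a list of such tracks.
#' @export
predict_track <- function(net, segment) {
  single <- is.null(dim(segment))
  xmat <- if (single) matrix(segment, ncol = 1) else segment
  if (any(!is.finite(xmat))) stop_spindlr("non-finite input samples")
  Tt <- nrow(xmat)
  X <- pad_batch(xmat, net$config$pools)
  P <- net_forward(net, X, training = FALSE)$P
  tracks <- lapply(seq_len(ncol(xmat)), function(b) {
    structure(list(spindle = P[1, seq_len(Tt), b],
                   no_spindle = P[2, seq_len(Tt), b],
                   fs = net$config$fs),
              class = "probability_track")
  })
  if (single) tracks[[1]] else tracks
}
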