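# Parameter counts are checked against a closed-form sum over the declared
# layer shapes, written out independently of build_model's bookkeeping.

conv_n <- function(c_in, c_out, k) c_out * k * c_in + c_out
bn_n <- function(c) 2 * c

test_that("parameter count equals the closed-form sum over layer shapes", {
  cfg <- model_config()                 # 3 levels, (16, 32, 64), k = 9
  f <- c(16, 32, 64); k <- 9
  expected <-
    conv_n(1, f[1], k) + conv_n(f[1], f[1], k) + 2 * bn_n(f[1]) +   # enc 1
    conv_n(f[1], f[2], k) + conv_n(f[2], f[2], k) + 2 * bn_n(f[2]) + # enc 2
    conv_n(f[2], f[3], k) + conv_n(f[3], f[3], k) + 2 * bn_n(f[3]) + # bottleneck
    conv_n(f[3], f[3] / 2, 4) +                                      # up-conv 2
    conv_n(f[2] + f[3] / 2, f[2], k) + conv_n(f[2], f[2], k) + 2 * bn_n(f[2]) +
    conv_n(f[2], f[2] / 2, 4) +                                      # up-conv 1
    conv_n(f[1] + f[2] / 2, f[1], k) + conv_n(f[1], f[1], k) + 2 * bn_n(f[1]) +
    conv_n(f[1], 2, 1)                                               # head
  expect_equal(count_params(build_model(cfg, seed = 1)), expected)
})

test_that("configuration contracts are enforced", {
  expect_error(model_config(levels = 3, filters = c(16, 32)), "one entry per level")
  expect_error(model_config(levels = 2, filters = c(16, 48), pools = 4), "double")
  expect_error(model_config(pools = c(4)), "length levels - 1")
  cfg <- model_config(levels = 2, filters = c(16, 32), pools = c(4))
  net <- build_model(cfg, seed = 1)
  tr <- predict_track(net, rnorm(400))
  expect_length(tr$spindle, 400)
})

test_that("forward pass preserves length and normalization on 115 s input", {
  net <- build_model(model_config(levels = 2, filters = c(4, 8), pools = c(4)),
                     seed = 2)
  x <- rnorm(11500)                    # 11500 not divisible by 4: padding path
  tr <- predict_track(net, x)
  expect_length(tr$spindle, 11500)
  expect_true(all(tr$spindle >= 0 & tr$spindle <= 1))
  expect_true(all(tr$no_spindle >= 0 & tr$no_spindle <= 1))
  expect_lt(max(abs(tr$spindle + tr$no_spindle - 1)), 1e-6)

  tr2 <- predict_track(net, x)         # inference is deterministic
  expect_identical(tr$spindle, tr2$spindle)

  expect_error(predict_track(net, c(rnorm(100), NA)), "non-finite")
})

test_that("receptive field reproduces the printed calibration", {
  rf_s <- function(w2) receptive_field(model_config(pools = c(4, w2)), "seconds")
  expect_equal(rf_s(1), 1.48)
  expect_equal(rf_s(4), 3.52)
  expect_equal(rf_s(8), 6.24)
  # affine in w2 with slope 4 + 8 * (k - 1) * d = 68 samples per unit w2,
  # which holds only at effective extent (k - 1) * d = 8 per convolution
  rf <- function(w2) receptive_field(model_config(pools = c(4, w2)))
  expect_equal(diff(sapply(1:5, rf)), rep(68, 4))
  # the same receptive fields arise from the dilated equivalent calibration
  expect_equal(receptive_field(model_config(kernel = 3, dilation = 4,
                                            pools = c(4, 4))), 352)
})

test_that("compiled convolution agrees with the pure-R reference", {
  set.seed(31)
  for (i in 1:6) {
    C <- sample(1:6, 1); Cout <- sample(1:6, 1)
    k <- sample(c(1, 3, 4, 9), 1)
    d <- if (k > 1) sample(1:4, 1) else 1
    Tt <- sample(20:50, 1); B <- sample(1:3, 1)
    X <- array(rnorm(C * Tt * B), c(C, Tt, B))
    p <- list(W = matrix(rnorm(Cout * k * C), Cout), b = rnorm(Cout),
              k = k, d = d)
    expect_equal(spindlr:::conv_fwd(X, p), spindlr:::conv_fwd_ref(X, p),
                 tolerance = 1e-12)
    dY <- array(rnorm(Cout * Tt * B), c(Cout, Tt, B))
    got <- spindlr:::conv_bwd(dY, X, p)
    ref <- spindlr:::conv_bwd_ref(dY, X, p)
    expect_equal(got$dX, ref$dX, tolerance = 1e-12)
    expect_equal(got$dW, ref$dW, tolerance = 1e-12)
    expect_equal(as.numeric(got$db), ref$db, tolerance = 1e-12)
  }
})

test_that("output is translation-covariant on interior samples", {
  cfg <- model_config(levels = 3, filters = c(4, 8, 16), pools = c(2, 2))
  net <- build_model(cfg, seed = 5)
  P <- prod(cfg$pools)                  # one pooling-product stride
  set.seed(6)
  Tt <- 512
  x <- rnorm(Tt)
  x_shift <- c(x[(P + 1):Tt], x[1:P])   # circular shift by P samples
  a <- predict_track(net, x)$spindle
  b <- predict_track(net, x_shift)$spindle
  margin <- receptive_field(cfg)
  interior <- (margin + 1):(Tt - margin - P)
  expect_equal(b[interior], a[interior + P], tolerance = 1e-8)
})

test_that("initialization is seed-deterministic and Kaiming-bounded", {
  cfg <- model_config(levels = 2, filters = c(8, 16), pools = c(4))
  n1 <- build_model(cfg, seed = 42)
  n2 <- build_model(cfg, seed = 42)
  n3 <- build_model(cfg, seed = 43)
  expect_identical(n1$params, n2$params)
  expect_false(identical(n1$params$e1c1$W, n3$params$e1c1$W))
  for (nm in names(n1$params)) {
    p <- n1$params[[nm]]
    if (is.null(p$W)) next
    bound <- sqrt(6 / (p$k * p$c_in))
    expect_true(all(abs(p$W) <= bound), label = paste("bound", nm))
  }
})
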