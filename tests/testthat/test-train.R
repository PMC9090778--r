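test_that("generalized dice loss: limits, hand value, symmetry, bounds", {
  r <- c(1, 1, 0, 0)
  expect_equal(gdice_loss(r, r), 0)                 # perfect prediction
  # uniform 0.5 prediction on a balanced 4-sample batch: direct substitution
  # of the formula gives 1 - 2 * 0.5 / 2 = 0.5
  expect_equal(gdice_loss(rep(0.5, 4), r), 0.5)
  # swapping class labels of both target and prediction leaves it unchanged
  set.seed(14)
  p <- runif(50); t <- rbinom(50, 1, 0.3)
  expect_equal(gdice_loss(p, t), gdice_loss(1 - p, 1 - t))
  for (i in 1:20) {
    p <- runif(30); t <- rbinom(30, 1, runif(1))
    l <- gdice_loss(p, t)
    expect_gte(l, 0); expect_lte(l, 1)
  }
  # absent class: epsilon floor keeps the loss finite
  expect_true(is.finite(gdice_loss(runif(10), rep(0, 10))))
  expect_error(gdice_loss(c(2, 0.5), c(1, 0)), "\\[0, 1\\]")
})

test_that("backprop gradients match central finite differences", {
  set.seed(42)
  cfg <- model_config(levels = 3, filters = c(2, 4, 8), kernel = 3,
                      pools = c(2, 2))
  net <- build_model(cfg, seed = 3)
  Tt <- 37; B <- 2                     # odd length exercises the padding path
  xmat <- matrix(rnorm(Tt * B), Tt, B)
  tgt <- matrix(rbinom(Tt * B, 1, 0.3), Tt, B)
  X <- spindlr:::pad_batch(xmat, cfg$pools)
  loss_of <- function(net) {
    fb <- spindlr:::net_forward(net, X, training = TRUE)
    Pc <- fb$P[, seq_len(Tt), , drop = FALSE]
    dim(Pc) <- c(2, Tt, B)
    R <- array(0, dim(Pc)); R[1, , ] <- tgt; R[2, , ] <- 1 - tgt
    spindlr:::gdice_fwd(Pc, R)$loss
  }
  fb <- spindlr:::net_forward(net, X, training = TRUE, keep_cache = TRUE)
  Pc <- fb$P[, seq_len(Tt), , drop = FALSE]
  dim(Pc) <- c(2, Tt, B)
  R <- array(0, dim(Pc)); R[1, , ] <- tgt; R[2, , ] <- 1 - tgt
  fw <- spindlr:::gdice_fwd(Pc, R)
  dP <- array(0, dim(fb$P))
  dP[, seq_len(Tt), ] <- spindlr:::gdice_bwd(Pc, R, fw)
  grads <- spindlr:::net_backward(net, fb$cache, dP)
  eps <- 1e-6
  for (nm in names(grads)) {
    for (slot in names(grads[[nm]])) {
      g <- grads[[nm]][[slot]]
      for (ii in sample(length(g), min(3, length(g)))) {
        n2 <- net
        n2$params[[nm]][[slot]][ii] <- n2$params[[nm]][[slot]][ii] + eps
        lp <- loss_of(n2)
        n2$params[[nm]][[slot]][ii] <- n2$params[[nm]][[slot]][ii] - 2 * eps
        lm <- loss_of(n2)
        fd <- (lp - lm) / (2 * eps)
        expect_lt(abs(fd - g[ii]) / max(abs(fd), abs(g[ii]), 1e-8), 1e-4)
      }
    }
  }
})

test_that("run configuration validates its invariants", {
  expect_error(run_config(batch_size = 0), "batch_size")
  expect_error(run_config(patience = 900, max_epochs = 800), "patience")
  expect_error(run_config(grid = c(0, 0.5)), "grid")
  expect_equal(steps_per_epoch(535, 12), 45L)
  expect_equal(steps_per_epoch(12, 12), 1L)
})

test_that("by-subject folds balance ten-segment subjects and sizes", {
  # the 180-subject layout: 144 training subjects, 30 of them ten-segment
  manifest <- data.frame(
    subject_id = c(rep(sprintf("t%02d", 1:30), each = 10),
                   rep(sprintf("r%03d", 1:114), each = 3)),
    cohort = "younger")
  manifest$segment_id <- paste0(manifest$subject_id, "_",
                                stats::ave(seq_len(nrow(manifest)),
                                           manifest$subject_id, FUN = seq_along))
  folds <- kfold_by_subject(manifest, k = 6, seed = 2)
  expect_length(folds, 144)
  expect_equal(as.vector(table(folds)), rep(24, 6))
  ten_ids <- sprintf("t%02d", 1:30)
  expect_equal(as.vector(table(folds[ten_ids])), rep(5, 6))
  seg_per_fold <- sapply(1:6, function(i) {
    sum(manifest$subject_id %in% names(folds)[folds == i])
  })
  expect_equal(seg_per_fold, rep(107, 6))
  expect_equal(steps_per_epoch(sum(seg_per_fold[-1]), 12), 45L)
  # all segments of any subject lie in a single fold by construction
  expect_true(all(tapply(folds[manifest$subject_id], manifest$subject_id,
                         function(x) length(unique(x))) == 1))
  # determinism and k > n error
  expect_identical(folds, kfold_by_subject(manifest, k = 6, seed = 2))
  small <- manifest[manifest$subject_id %in% sprintf("t%02d", 1:6), ]
  expect_equal(as.vector(table(kfold_by_subject(small, k = 6, seed = 1))),
               rep(1, 6))
  expect_error(kfold_by_subject(small, k = 10, seed = 1), "exceeds")
})

test_that("Kaiming re-initialization is seeded and bounded", {
  cfg <- model_config(levels = 2, filters = c(4, 8), pools = c(2))
  net <- build_model(cfg, seed = 1)
  a <- init_params(net, seed = 11)
  b <- init_params(net, seed = 11)
  c <- init_params(net, seed = 12)
  expect_identical(a$params, b$params)
  expect_false(identical(a$params$e1c2$W, c$params$e1c2$W))
  w <- a$params$e1c2$W                  # fan_in = 9 * 4
  expect_lte(max(abs(w)), sqrt(6 / 36))
})

test_that("early stopping honours patience and keeps the best epoch", {
  cfg_s <- synth_config(segment_s = 8, snr = 3)
  ds <- generate_dataset(cfg_s, n_younger = 4, n_older = 0, seed = 6)
  ds$segments <- lapply(ds$segments, zscore)
  mcfg <- model_config(levels = 2, filters = c(4, 8), pools = c(4),
                       moving_avg_s = 0.1)
  # patience 1 with a metric that cannot improve after epoch 1's entry:
  # epoch 1 always improves over -Inf, epoch 2 must stop
  run <- run_config(batch_size = 4, patience = 1, max_epochs = 10,
                    val_metric = "f1_20")
  subj <- unique(ds$manifest$subject_id)
  res <- train_fold(ds, subj[1:3], subj[4], mcfg, run, seed = 2)
  expect_lte(nrow(res$history), 1 + which.max(res$history$val_metric))
  expect_equal(res$best_metric, max(res$history$val_metric))
  # best-epoch parameters are the ones returned: metric recomputes identically
  m <- ds$manifest
  va <- spindlr:::segment_matrices(ds, m$segment_id[m$subject_id == subj[4]])
  ref <- ds$annotations[m$segment_id[m$subject_id == subj[4]]]
  expect_equal(spindlr:::validation_metric(res$net, va$X, ref, run),
               res$best_metric)
  expect_error(train_fold(ds, subj[1:3], subj[3], mcfg, run, seed = 1),
               "disjoint")
  expect_error(train_fold(ds, subj, character(0), mcfg, run, seed = 1),
               "empty")
})

test_that("cross-validation is seed-reproducible with per-fold metrics", {
  cfg_s <- synth_config(segment_s = 8, snr = 3)
  ds <- generate_dataset(cfg_s, n_younger = 6, n_older = 0, seed = 7)
  ds$segments <- lapply(ds$segments, zscore)
  mcfg <- model_config(levels = 2, filters = c(4, 8), pools = c(4),
                       moving_avg_s = 0.1)
  run <- run_config(batch_size = 6, patience = 2, max_epochs = 2,
                    folds = 3, val_metric = "f1_20")
  cv1 <- cross_validate(ds, mcfg, run, seed = 5)
  cv2 <- cross_validate(ds, mcfg, run, seed = 5)
  expect_identical(cv1$fold_metrics, cv2$fold_metrics)
  expect_identical(cv1$histories, cv2$histories)
  expect_length(cv1$fold_metrics, 3)
  expect_equal(cv1$sd, sd(cv1$fold_metrics))
})
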