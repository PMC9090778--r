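# Generalized-dice training with Adam, by-subject k-fold cross-validation,
# and validation-F1-based early stopping / model selection. The loss is
# computed on the raw (unsmoothed) probability tracks; moving-average
# smoothing belongs to inference only.

#' Training run configuration
#'
#' Defaults follow the published recipe: Adam with learning rate 0.005,
#' `beta1 = 0.9`, `beta2 = 0.999`, `eps = 1e-8`; minibatches of 12
#' segments; early stopping after 300 epochs without validation
#' improvement, hard cap at 800 epochs; 6 folds. The per-epoch validation
#' metric is F1-bar (the F1 integral over the overlap-threshold grid);
#' `val_metric = "f1_20"` switches to plain F1 at the 20% threshold.
#'
#' @param lr,beta1,beta2,eps Adam hyperparameters.
#' @param batch_size Segments per minibatch (`>= 1`).
#' @param patience Epochs without improvement before stopping
#'   (`<= max_epochs`).
#' @param max_epochs Hard epoch cap.
#' @param folds Number of cross-validation folds.
#' @param grid Overlap-threshold grid for evaluation, within `(0, 1]`.
#' @param val_metric `"f1bar"` or `"f1_20"`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(lr = 0.005, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                       batch_size = 12, patience = 300, max_epochs = 800,
                       folds = 6, grid = seq(0.05, 1, by = 0.05),
                       val_metric = c("f1bar", "f1_20")) {
  if (batch_size < 1) stop_spindlr("batch_size must be >= 1")
  if (patience > max_epochs) stop_spindlr("patience must be <= max_epochs")
  if (any(grid <= 0) || any(grid > 1)) stop_spindlr("grid must lie in (0, 1]")
  structure(list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps,
                 batch_size = batch_size, patience = patience,
                 max_epochs = max_epochs, folds = folds, grid = grid,
                 val_metric = match.arg(val_metric)),
            class = "run_config")
}

#' Number of optimizer steps per training epoch
#'
#' One epoch iterates once over the training segments in minibatches, the
#' last (possibly short) batch included, hence the ceiling.
#'
#' @param n_segments Training-set size in segments.
#' @param batch_size Minibatch size.
#' @return Integer step count.
#' @export
steps_per_epoch <- function(n_segments, batch_size) {
  as.integer(ceiling(n_segments / batch_size))
}

#' Generalized dice loss
#'
#' `loss = 1 - 2 * (sum_l w_l sum_n r_ln p_ln) /
#' (sum_l w_l sum_n (r_ln + p_ln))` over the two classes l (spindle,
#' no-spindle) and all samples n of the batch, with class weights
#' `w_l = 1 / (sum_n r_ln)^2` (epsilon-floored when a class is absent).
#' Zero iff the prediction equals the one-hot target with both classes
#' present; bounded in `[0, 1]`; symmetric under a joint class swap.
#'
#' @param spindle_prob Predicted spindle probabilities (vector, matrix or
#'   array); the no-spindle channel is its complement.
#' @param target Binary labels of the same shape (1 = spindle).
#' @return The scalar loss.
#' @export
gdice_loss <- function(spindle_prob, target) {
  p <- as.numeric(spindle_prob)
  r <- as.numeric(target)
  if (length(p) != length(r)) stop_spindlr("shape mismatch")
  if (any(p < -1e-9) || any(p > 1 + 1e-9))
    stop_spindlr("probabilities must lie in [0, 1]")
  P <- rbind(p, 1 - p)
  R <- rbind(r, 1 - r)
  dim(P) <- c(2, length(p), 1)
  dim(R) <- dim(P)
  gdice_fwd(P, R)$loss
}

#' By-subject k-fold split
#'
#' Subjects (never segments) are assigned to folds. Ten-segment subjects
#' are dealt round-robin first so each fold receives an equal share of
#' them; the remaining subjects are then distributed at random so that
#' fold sizes (in subjects) differ by at most one.
#'
#' @param manifest Data frame with columns `subject_id` and `segment_id`.
#' @param k Number of folds.
#' @param seed Seed making the split deterministic.
#' @return Named integer vector: subject_id -> fold index in `1..k`.
#' @export
kfold_by_subject <- function(manifest, k = 6, seed = 1) {
  counts <- table(manifest$subject_id)
  subjects <- names(counts)
  if (k > length(subjects))
    stop_spindlr("k (", k, ") exceeds the number of subjects (",
                 length(subjects), ")")
  with_seed(seed, {
    ten <- sample(subjects[counts == 10])
    rest <- sample(subjects[counts != 10])
    fold <- integer(0)
    fold[ten] <- (seq_along(ten) - 1L) %% k + 1L
    n <- length(subjects)
    target <- rep(n %/% k, k) + (seq_len(k) <= n %% k)
    capacity <- target - tabulate(fold[ten], nbins = k)
    if (any(capacity < 0))
      stop_spindlr("ten-segment subjects cannot be balanced into ", k,
                   " equal folds")
    fold[rest] <- rep(seq_len(k), capacity)
    fold[subjects]
  })
}

# Assemble the T x n sample matrix and 0/1 target matrix for a set of
# segment ids; all segments must share one length.
segment_matrices <- function(dataset, seg_ids) {
  lens <- vapply(dataset$segments[seg_ids], length, 1L)
  if (length(unique(lens)) != 1)
    stop_spindlr("segments must share one length for batched training")
  Tt <- lens[1]
  fs <- dataset$config$fs
  X <- vapply(seg_ids, function(s) dataset$segments[[s]], numeric(Tt))
  Y <- vapply(seg_ids, function(s)
    as.numeric(events_to_indicator(dataset$annotations[[s]], Tt, fs)),
    numeric(Tt))
  list(X = matrix(X, Tt), Y = matrix(Y, Tt))
}

validation_metric <- function(net, Xval, ref, run) {
  det <- predict_events(net, Xval)
  if (run$val_metric == "f1_20") {
    tp <- fp <- fn <- 0L
    for (s in seq_along(ref)) {
      m <- match_events(det[[s]], ref[[s]], 0.2)
      tp <- tp + m$tp; fp <- fp + m$fp; fn <- fn + m$fn
    }
    event_prf(list(tp = tp, fp = fp, fn = fn))$f1
  } else {
    f1_curve(det, ref, run$grid)$f1_bar
  }
}

#' Train one fold
#'
#' Per epoch: iterate once over the training segments in shuffled
#' minibatches (generalized dice loss, Adam update), then compute the
#' validation metric with the full inference chain. The parameters of the
#' best validation epoch are kept; training stops once the metric has not
#' improved for `run$patience` epochs, or at `run$max_epochs`.
#'
#' @param dataset A dataset from [generate_dataset()] (or same shape:
#'   `manifest`, `segments`, `annotations`, `config$fs`).
#' @param train_subjects,val_subjects Disjoint subject-id sets.
#' @param config A [model_config()].
#' @param run A [run_config()].
#' @param seed Seed covering initialization and batch shuffling.
#' @return A list with `net` (best parameters), `history` (data frame:
#'   epoch, loss, val_metric), `best_metric`, `best_epoch`.
#' @export
train_fold <- function(dataset, train_subjects, val_subjects, config, run,
                       seed = 1) {
  m <- dataset$manifest
  tr_segs <- m$segment_id[m$subject_id %in% train_subjects]
  va_segs <- m$segment_id[m$subject_id %in% val_subjects]
  if (length(tr_segs) == 0 || length(va_segs) == 0)
    stop_spindlr("empty training or validation set")
  if (length(intersect(train_subjects, val_subjects)) > 0)
    stop_spindlr("train and validation subjects must be disjoint")
  tr <- segment_matrices(dataset, tr_segs)
  va <- segment_matrices(dataset, va_segs)
  ref <- dataset$annotations[va_segs]
  Tt <- nrow(tr$X)

  with_seed(seed, {
    net <- build_model(config)
    opt <- adam_init(net$params)
    best <- -Inf; best_params <- net$params; best_bufs <- net$bufs
    best_epoch <- 0L; since <- 0L
    history <- vector("list", run$max_epochs)
    n_tr <- ncol(tr$X)
    for (epoch in seq_len(run$max_epochs)) {
      ord <- sample.int(n_tr)
      losses <- numeric(0)
      for (b0 in seq(1, n_tr, by = run$batch_size)) {
        idx <- ord[b0:min(b0 + run$batch_size - 1, n_tr)]
        Xb <- pad_batch(tr$X[, idx, drop = FALSE], config$pools)
        tgt <- tr$Y[, idx, drop = FALSE]
        fb <- net_forward(net, Xb, training = TRUE, keep_cache = TRUE)
        net$bufs <- fb$bufs
        Pc <- fb$P[, seq_len(Tt), , drop = FALSE]
        dim(Pc) <- c(2, Tt, length(idx))
        R <- array(0, dim(Pc))
        R[1, , ] <- tgt
        R[2, , ] <- 1 - tgt
        fw <- gdice_fwd(Pc, R)
        losses <- c(losses, fw$loss)
        dP <- array(0, dim(fb$P))
        dP[, seq_len(Tt), ] <- gdice_bwd(Pc, R, fw)
        grads <- net_backward(net, fb$cache, dP)
        upd <- adam_step(net$params, grads, opt, lr = run$lr,
                         beta1 = run$beta1, beta2 = run$beta2, eps = run$eps)
        net$params <- upd$params
        opt <- upd$state
      }
      vm <- validation_metric(net, va$X, ref, run)
      history[[epoch]] <- data.frame(epoch = epoch, loss = mean(losses),
                                     val_metric = vm)
      if (vm > best) {
        best <- vm; best_params <- net$params; best_bufs <- net$bufs
        best_epoch <- epoch; since <- 0L
      } else {
        since <- since + 1L
      }
      if (since >= run$patience) break
    }
    net$params <- best_params
    net$bufs <- best_bufs
    list(net = net, history = do.call(rbind, history[!vapply(history, is.null, TRUE)]),
         best_metric = best, best_epoch = best_epoch)
  })
}

#' By-subject k-fold cross-validation
#'
#' Runs [train_fold()] once per fold (the fold is the validation set, all
#' other subjects train) and summarizes the best validation metrics as
#' mean and standard deviation across folds.
#'
#' @param dataset A dataset (see [train_fold()]).
#' @param config A [model_config()].
#' @param run A [run_config()].
#' @param seed Seed; fold assignment and each fold's training derive their
#'   seeds from it.
#' @return A list with `folds` (subject -> fold), `models`, `histories`,
#'   `fold_metrics`, `mean`, `sd`.
#' @export
cross_validate <- function(dataset, config, run, seed = 1) {
  folds <- kfold_by_subject(dataset$manifest, k = run$folds, seed = seed)
  subjects <- names(folds)
  models <- vector("list", run$folds)
  histories <- vector("list", run$folds)
  metrics <- numeric(run$folds)
  for (i in seq_len(run$folds)) {
    val <- subjects[folds == i]
    tr <- subjects[folds != i]
    res <- train_fold(dataset, tr, val, config, run,
                      seed = (seed * 131L + i) %% .Machine$integer.max)
    models[[i]] <- res$net
    histories[[i]] <- res$history
    metrics[i] <- res$best_metric
  }
  list(folds = folds, models = models, histories = histories,
       fold_metrics = metrics, mean = mean(metrics), sd = stats::sd(metrics))
}
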