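test_that("relative overlap: identity, disjoint, hand-computed case", {
  expect_equal(relative_overlap(c(2, 1), c(2, 1)), 1)
  expect_equal(relative_overlap(c(0, 1), c(5, 1)), 0)
  # [0,1) vs [0.5,1.5): intersection 0.5, union 1.5
  expect_equal(relative_overlap(c(0, 1), c(0.5, 1)), 1 / 3)
  expect_error(relative_overlap(c(0, 0), c(0, 1)), "positive duration")
})

test_that("matching counts satisfy the definitional contracts", {
  ev <- event_list(c(1, 3, 6), c(0.5, 0.8, 1))
  for (th in c(0.1, 0.5, 0.9)) {
    m <- match_events(ev, ev, th)
    expect_equal(m$tp, 3L)
    expect_equal(m$fp, 0L)
    expect_equal(m$fn, 0L)
  }
  m <- match_events(event_list(), ev, 0.2)
  expect_equal(c(m$tp, m$fp, m$fn), c(0L, 0L, 3L))
})

test_that("greedy matching agrees with exhaustive optimal assignment", {
  set.seed(21)
  n_diff <- 0L
  n_cases <- 200
  for (i in seq_len(n_cases)) {
    det <- random_events(sample(0:6, 1), span = 15)
    ref <- random_events(sample(0:6, 1), span = 15)
    th <- sample(c(0.01, 0.2, 0.5), 1)
    got <- match_events(det, ref, th)$tp
    opt <- brute_force_tp(det, ref, th)
    expect_lte(abs(got - opt), 1L)
    if (got != opt) n_diff <- n_diff + 1L
  }
  expect_lt(n_diff / n_cases, 0.05)
})

test_that("recall/precision/F1 formulas and empty-denominator conventions", {
  pr <- event_prf(list(tp = 1, fp = 1, fn = 1))
  expect_equal(pr$recall, 0.5)
  expect_equal(pr$precision, 0.5)
  expect_equal(pr$f1, 0.5)
  all_empty <- event_prf(list(tp = 0, fp = 0, fn = 0))
  expect_equal(unlist(all_empty), c(recall = 1, precision = 1, f1 = 1))
  expect_equal(event_prf(list(tp = 0, fp = 3, fn = 0))$recall, 0)
  expect_equal(event_prf(list(tp = 0, fp = 0, fn = 2))$precision, 0)
  # F1 is the harmonic mean of precision and recall when both are defined
  set.seed(2)
  for (i in 1:25) {
    cnt <- list(tp = sample(1:9, 1), fp = sample(0:9, 1), fn = sample(0:9, 1))
    pr <- event_prf(cnt)
    expect_equal(pr$f1, 2 * pr$precision * pr$recall / (pr$precision + pr$recall))
  }
})

test_that("swapping detected and reference swaps recall and precision", {
  set.seed(5)
  a <- random_events(5); b <- random_events(4)
  ma <- event_prf(match_events(a, b, 0.2))
  mb <- event_prf(match_events(b, a, 0.2))
  expect_equal(ma$recall, mb$precision)
  expect_equal(ma$precision, mb$recall)
  expect_equal(ma$f1, mb$f1)
})

test_that("F1 curve is non-increasing and F1-bar normalizes constants", {
  set.seed(7)
  for (i in 1:30) {
    det <- random_events(sample(1:6, 1), span = 12)
    ref <- random_events(sample(1:6, 1), span = 12)
    fc <- f1_curve(det, ref)
    expect_true(all(diff(fc$curve$f1) <= 1e-12))
  }
  ev <- random_events(5)
  fc <- f1_curve(ev, ev, grid = seq(0.05, 0.95, by = 0.05))
  expect_equal(fc$curve$f1, rep(1, nrow(fc$curve)))
  expect_equal(fc$f1_bar, 1)
  expect_error(f1_curve(ev, ev, grid = 0.2), "grid")
})

test_that("subject summaries pool events across segments", {
  ev <- lapply(1:3, function(i) event_list(c(10, 50) * i / 3, c(0.6, 0.9)))
  s <- subject_summary(ev, total_minutes = 3 * 115 / 60)
  expect_equal(s$density, 6 / (345 / 60), tolerance = 1e-12)  # ~1.043 / min
  expect_equal(s$mean_duration, 0.75)
  empty <- subject_summary(list(event_list()), 5)
  expect_equal(empty$density, 0)
  expect_true(empty$no_events)
  expect_true(is.na(empty$mean_duration))
  expect_error(subject_summary(ev, 0), "total_minutes")
})

test_that("summary comparison recovers exact and scaled relationships", {
  ref <- c(1, 2.5, 4, 5.25, 3.1, 0.9)
  cs <- compare_summaries(ref, ref)
  expect_equal(cs$r, 1)
  expect_equal(cs$slope, 1)
  cs2 <- compare_summaries(2 * ref, ref)
  expect_equal(cs2$r, 1)
  expect_equal(cs2$slope, 2)
  expect_equal(compare_summaries(ref, rev(ref))$fisher_z,
               atanh(cor(ref, rev(ref))))
  expect_error(compare_summaries(rep(1, 6), ref), "zero variance")
})

test_that("summary comparison recovers slope and r under known noise", {
  set.seed(19)
  ref <- runif(60, 0.5, 6)
  pred <- 0.9 * ref + rnorm(60, sd = 0.3)
  cs <- compare_summaries(pred, ref)
  expect_equal(cs$slope, 0.9, tolerance = 0.12)
  r_true <- 0.9 * sd(ref) / sqrt(0.9^2 * var(ref) + 0.3^2)
  expect_equal(cs$r, r_true, tolerance = 0.05)
})

test_that("Fisher z-test degenerates to zero for equal correlations", {
  ft <- fisher_z_test(0.8, 20, 0.8, 20)
  expect_equal(ft$z, 0)
  expect_equal(ft$p, 1)
  expect_equal(atanh(0), 0)
  expect_error(fisher_z_test(0.5, 3, 0.5, 10), "n > 3")
})

test_that("test-split selection returns the median-scoring candidate", {
  cfg <- synth_config(segment_s = 20)
  ds <- generate_dataset(cfg, n_younger = 8, n_older = 8, n_ten = 0, seed = 4)
  # cheap deterministic stand-in detector: echo sigma-power threshold runs
  det_fun <- function(x, fs) sigma_baseline_detector(zscore(x), fs)
  sel <- select_test_split(ds, det_fun, n_candidates = 5,
                           n_test_per_cohort = 2, seed = 9)
  expect_equal(sel$score, sort(sel$scores)[3])     # 3rd of 5 order statistic
  expect_length(sel$test_subjects, 4)
  expect_length(sel$train_subjects, 12)
  sel2 <- select_test_split(ds, det_fun, n_candidates = 5,
                            n_test_per_cohort = 2, seed = 9)
  expect_identical(sel$test_subjects, sel2$test_subjects)
  sel1 <- select_test_split(ds, det_fun, n_candidates = 1,
                            n_test_per_cohort = 2, seed = 10)
  expect_equal(sel1$score, sel1$scores[1])
  expect_error(select_test_split(ds, det_fun, n_test_per_cohort = 9, seed = 1),
               "not enough")
})

test_that("sigma baseline: high-SNR recall, background specificity, limits", {
  tp <- fn <- 0L
  for (s in 1:4) {
    su <- generate_subject(synth_config(snr = 5), 1, seed = 100 + s)
    det <- sigma_baseline_detector(zscore(su$segments[[1]]), 100)
    m <- match_events(det, su$annotations[[1]], 0.2)
    tp <- tp + m$tp; fn <- fn + m$fn
  }
  expect_gte(tp / (tp + fn), 0.9)

  fp <- 0L; mins <- 0
  for (s in 1:4) {
    bg <- zscore(generate_background(synth_config(), 11500, seed = 200 + s))
    fp <- fp + nrow(sigma_baseline_detector(bg, 100))
    mins <- mins + 115 / 60
  }
  expect_lte(fp / mins, 1)

  x <- zscore(generate_background(synth_config(), 2000, seed = 1))
  expect_equal(nrow(sigma_baseline_detector(x, 100, rel_threshold = 1e9)), 0)
})
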