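test_that("spatial PCA reconstructs low-rank data and orders variance", {
  set.seed(21)
  # rank-3 spatial structure on 8 channels
  mixing <- matrix(rnorm(8 * 3), 8, 3)
  src <- array(rnorm(10 * 3 * 50), c(10, 3, 50))
  data <- array(0, c(10, 8, 50))
  for (i in 1:10) data[i, , ] <- mixing %*% src[i, , ]
  e <- tiny_epochs(n = 10, nch = 8, nt = 50)
  e$data <- data
  f <- pca_reduce(e, 3)
  # reconstruction from 3 components is exact
  for (i in c(1, 7)) {
    rec <- f$rotation %*% f$data[i, , ] + f$center
    expect_equal(rec, data[i, , ], tolerance = 1e-8)
  }
  expect_true(all(diff(f$var_explained) <= 1e-8))
  # requesting more components than the rank names the achievable rank
  expect_error(pca_reduce(e, 5), "rank 3")
})

test_that("white-noise data spreads variance evenly over components", {
  set.seed(22)
  e <- tiny_epochs(n = 30, nch = 61, nt = 40)
  e$data <- array(rnorm(length(e$data)), dim(e$data))
  f <- pca_reduce(e, 15)
  frac <- sum(f$var_explained[1:15]) / sum(f$var_explained)
  # slightly above 15/61 because the top eigenvalues absorb sampling noise
  expect_gt(frac, 15 / 61)
  expect_lt(frac, 15 / 61 + 0.12)
})

test_that("bin_average makes near-equal random partitions", {
  x <- matrix(rnorm(56 * 4), 56, 4)
  ba <- bin_average(x, 10, seed = 3)
  sizes <- as.vector(table(ba$assignment))
  expect_equal(sort(sizes), c(rep(5, 4), rep(6, 6)))  # 56 = 6x6 + 4x5
  expect_equal(dim(ba$means), c(10, 4))
  ba30 <- bin_average(matrix(1, 30, 2), 3, seed = 1)
  expect_equal(as.vector(table(ba30$assignment)), c(10, 10, 10))
  # identical trials -> every sub-ERP equals the common row
  expect_true(all(ba30$means == 1))
  # deterministic given seed
  expect_identical(bin_average(x, 10, seed = 3)$assignment, ba$assignment)
  expect_error(bin_average(x[1:5, ], 10), "fewer")
})

test_that("decoding finds a separable pattern only where it exists", {
  fe <- separable_features(k = 4, reps = 9, p = 10, nt = 3, signal_at = 3,
                           amp = 4, seed = 5)
  sp <- decode_spec("item_one_vs_all", n_iterations = 3, step = 20,
                    seed = 2)
  r <- decode_timecourse(fe, sp)
  expect_equal(r$times, c(0, 20, 40))
  expect_gt(r$accuracy[3], 0.95)
  expect_lt(abs(r$accuracy[2] - 0.25), 0.2)
  # confusion rows sum to the per-class test count
  expect_true(all(apply(r$confusion, c(1, 3), sum) ==
                    sp$n_iterations * sp$n_bins))
  # records reproduce the accuracy exactly when re-aggregated
  expect_equal(colMeans(r$pred == r$true), r$accuracy)
})

test_that("null data decodes at chance in both designs", {
  set.seed(6)
  accs2 <- replicate(6, {
    fe <- separable_features(k = 2, reps = 14, p = 8, nt = 1,
                             signal_at = integer(0), amp = 0,
                             seed = sample.int(1e6, 1))
    sp <- decode_spec("condition_pairwise", n_bins = 7, n_iterations = 2,
                      seed = sample.int(1e6, 1))
    decode_timecourse(fe, sp, labels = fe$trial_table$item_id)$accuracy
  })
  expect_lt(abs(mean(accs2) - 0.5), 0.1)
  fe <- separable_features(k = 12, reps = 6, p = 8, nt = 2,
                           signal_at = integer(0), amp = 0, seed = 9)
  sp <- decode_spec("item_one_vs_all", n_iterations = 4, seed = 4)
  r <- decode_timecourse(fe, sp)
  expect_lt(abs(mean(r$accuracy) - 1 / 12), 0.06)
})

test_that("item mode equalizes class counts to the least frequent", {
  fe <- separable_features(k = 3, reps = 8, p = 6, nt = 1, signal_at = 1,
                           amp = 5, seed = 7)
  # remove trials of the first class
  drop <- which(fe$trial_table$item_id == "it1")[1:3]
  fe$data <- fe$data[-drop, , , drop = FALSE]
  fe$trial_table <- fe$trial_table[-drop, ]
  sp <- decode_spec("item_one_vs_all", n_iterations = 2, seed = 1)
  r <- decode_timecourse(fe, sp)
  # balanced records: every class contributes bins x iterations outcomes
  expect_true(all(table(r$true) == sp$n_bins * sp$n_iterations))
})

test_that("train-only normalization survives a leakage probe", {
  # corrupting the test folds with a huge constant must not lift
  # null-data decoding above chance
  fe <- separable_features(k = 2, reps = 12, p = 8, nt = 2,
                           signal_at = integer(0), amp = 0, seed = 8)
  sp <- decode_spec("condition_pairwise", n_bins = 6, n_iterations = 3,
                    seed = 3)
  r <- decode_timecourse(fe, sp, labels = fe$trial_table$item_id,
                         test_offset = 1e6)
  expect_lt(mean(r$accuracy), 0.5 + 0.15)
})

test_that("accuracy is invariant to channel relabeling", {
  cfg <- small_cfg()
  sim <- simulate_participant(cfg, 1)
  e <- baseline_correct(sim$epochs, c(-500, 0))
  think <- select_trials(e, e$trial_table$condition == "Think")
  sp <- decode_spec("item_one_vs_all", n_iterations = 2, seed = 5)
  tps <- c(300, 1500)
  r1 <- decode_timecourse(pca_reduce(think), sp, timepoints = tps)
  perm <- sample(dim(think$data)[2])
  think2 <- think
  think2$data <- think$data[, perm, , drop = FALSE]
  think2$channel_names <- think$channel_names[perm]
  r2 <- decode_timecourse(pca_reduce(think2), sp, timepoints = tps)
  expect_equal(r1$accuracy, r2$accuracy, tolerance = 0.12)
})

test_that("iteration averaging is stable across seeds", {
  cfg <- small_cfg()
  sim <- simulate_participant(cfg, 1)
  e <- baseline_correct(sim$epochs, c(-500, 0))
  think <- select_trials(e, e$trial_table$condition == "Think")
  f <- pca_reduce(think)
  tps <- c(250, 1750)
  spa <- decode_spec("item_one_vs_all", n_iterations = 10, seed = 31)
  spb <- decode_spec("item_one_vs_all", n_iterations = 10, seed = 77)
  ra <- decode_timecourse(f, spa, timepoints = tps)
  rb <- decode_timecourse(f, spb, timepoints = tps)
  expect_lt(max(abs(ra$accuracy - rb$accuracy)), 0.12)
})

test_that("resampled item decoding reduces to plain decoding at full size", {
  fe <- separable_features(k = 4, reps = 6, p = 6, nt = 1, signal_at = 1,
                           amp = 5, seed = 2)
  sp <- decode_spec("item_one_vs_all", n_iterations = 1, seed = 9)
  rr <- decode_resampled_items(fe, sp, subset_size = 4, n_iterations = 3)
  expect_equal(rr$chance, 1 / 4)
  expect_gt(mean(rr$accuracy), 0.9)
  # null 12-item data, subsets of 6 -> accuracy about 1/6
  fe0 <- separable_features(k = 12, reps = 6, p = 6, nt = 1,
                            signal_at = integer(0), amp = 0, seed = 3)
  r0 <- decode_resampled_items(fe0, sp, subset_size = 6, n_iterations = 6)
  expect_lt(abs(mean(r0$accuracy) - 1 / 6), 0.08)
})

test_that("time-frequency decoding localizes band-limited signal", {
  sfreq <- 100
  times <- seq(-1000, 1500, by = 1000 / sfreq)
  nt <- length(times)
  k <- 3; reps <- 8; n <- k * reps; p <- 6
  set.seed(13)
  pats <- matrix(rnorm(k * p), k, p) * 3
  data <- array(rnorm(n * p * nt, 0, 1), c(n, p, nt))
  env <- as.numeric(times >= 0 & times < 1200)
  alpha_osc <- sin(2 * pi * 10 * times / 1000) * env
  for (i in 1:n) {
    cls <- (i - 1) %/% reps + 1
    data[i, , ] <- data[i, , ] + pats[cls, ] %o% alpha_osc
  }
  fe <- structure(list(data = data, times = times, sfreq = sfreq,
                       trial_table = data.frame(
                         condition = "Think",
                         item_id = rep(paste0("it", 1:k), each = reps))),
                  class = "feature_epochs")
  sp <- decode_spec("item_one_vs_all", n_iterations = 2, step = 200,
                    seed = 6)
  tf <- decode_timefrequency(fe, sp, freqs = c(3, 6, 10, 16, 25))
  theta <- mean(tf$accuracy[tf$freqs <= 6, tf$times >= 200 &
                              tf$times < 1000], na.rm = TRUE)
  alpha <- mean(tf$accuracy[tf$freqs == 10, tf$times >= 200 &
                              tf$times < 1000], na.rm = TRUE)
  expect_gt(alpha, 0.8)
  expect_lt(theta, alpha - 0.2)
  # band summary = mean over the selected bins
  bs <- tf_band_summary(tf, c(9, 12))
  ok <- !is.na(tf$accuracy[3, ])
  expect_equal(bs[ok], tf$accuracy[3, ok])
})

test_that("pairwise item decoding builds a symmetric RDM series", {
  fe <- separable_features(k = 4, reps = 6, p = 6, nt = 2,
                           signal_at = 2, amp = 5, seed = 10)
  # make items 1 and 2 identical in pattern
  i2 <- fe$trial_table$item_id == "it2"
  i1 <- which(fe$trial_table$item_id == "it1")
  fe$data[i2, , 2] <- fe$data[i1, , 2] +
    array(rnorm(sum(i2) * 6, 0, 0.5), c(sum(i2), 6))
  sp <- decode_spec("item_pairwise", n_iterations = 2, seed = 4)
  rs <- pairwise_item_decode(fe, sp)
  expect_equal(dim(unclass(rs)), c(4, 4, 2))
  m2 <- unclass(rs)[, , 2]
  expect_equal(m2, t(m2))
  expect_true(all(is.na(diag(m2))))
  # identical-pattern pair decodes near chance, distinct pairs above
  others <- c(m2[1, 3], m2[1, 4], m2[2, 3], m2[2, 4], m2[3, 4])
  expect_lt(m2[1, 2], min(others))
  expect_gt(mean(others), 0.85)
})
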