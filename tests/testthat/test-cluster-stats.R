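test_that("cluster formation matches hand-computed cases", {
  cl <- form_clusters(c(1.0, 2.5, 2.6, 0.3), 2.02, "time", "pos")
  expect_length(cl, 1)
  expect_equal(cl[[1]]$members, 2:3)
  expect_equal(cl[[1]]$mass, 5.1)
  expect_length(form_clusters(c(0.1, 1.9, 0.5), 2.02, "time", "pos"), 0)
  # negative tail
  cn <- form_clusters(c(-3, -2.5, 1, -2.6), 2.02, "time", "neg")
  expect_length(cn, 2)
  expect_equal(cn[[1]]$mass, -5.5)
  # 2-D grid with two disjoint blobs
  m <- matrix(0, 5, 6)
  m[1:2, 1:2] <- 3
  m[4:5, 5:6] <- 2.5
  cl2 <- form_clusters(m, 2, "grid", "pos")
  expect_length(cl2, 2)
  expect_setequal(vapply(cl2, `[[`, 0, "mass"), c(12, 10))
  expect_error(form_clusters(1:3, Inf), "finite")
})

test_that("1-D clustering agrees with a brute-force contiguous-run scan", {
  brute <- function(v, thr) {
    out <- list(); cur <- integer(0)
    for (i in seq_along(v)) {
      if (!is.na(v[i]) && v[i] > thr) cur <- c(cur, i)
      else if (length(cur)) { out[[length(out) + 1]] <- cur; cur <- integer(0) }
    }
    if (length(cur)) out[[length(out) + 1]] <- cur
    out
  }
  set.seed(31)
  for (rep in 1:1000) {
    v <- rnorm(sample(5:40, 1))
    thr <- runif(1, 0, 2)
    mine <- form_clusters(v, thr, "time", "pos")
    ref <- brute(v, thr)
    expect_equal(lapply(mine, `[[`, "members"), ref)
    expect_equal(vapply(mine, `[[`, 0, "mass"),
                 vapply(ref, function(ix) sum(v[ix]), 0))
  }
})

test_that("graph clustering groups only adjacent channels", {
  g <- structure(list(neighbors = list(2, c(1, 3), 2, 5, 4),
                      channel_names = letters[1:5]),
                 class = "neighbor_graph")
  v <- c(3, 3, 0, 3, 3)
  cl <- form_clusters(v, 2, g, "pos")
  expect_length(cl, 2)
  expect_equal(lapply(cl, `[[`, "members"), list(1:2, 4:5))
})

test_that("vs-chance permutation test recovers a planted effect", {
  set.seed(41)
  results <- lapply(1:8, function(p) {
    r <- null_decoding_result(k = 2, n_ex = 40, nt = 30)
    # plant an effect at timepoints 10..18: flip predictions toward truth
    for (tp in 10:18) {
      fix <- sample(40, 22)
      r$pred[fix, tp] <- r$true[fix]
    }
    r$accuracy <- colMeans(r$pred == r$true)
    r
  })
  ct <- perm_test_vs_chance(results, chance = 0.5, n_perm = 300,
                            time_range = c(0, 3000), seed = 5)
  expect_length(ct$null_pos, 300)
  expect_true(has_significant_cluster(ct, sign = "pos"))
  best <- ct$clusters[which.max(ct$clusters$mass), ]
  expect_lte(best$start, 10)
  expect_gte(best$end, 14)
  # corrected p monotone non-increasing in observed mass
  cl <- ct$clusters[order(ct$clusters$mass), ]
  expect_true(all(diff(cl$p) <= 1e-12 + 0))
  expect_error(perm_test_vs_chance(list(list(times = 1))), "records")
})

test_that("condition-difference test is silent for identical inputs", {
  set.seed(42)
  results <- lapply(1:6, function(p) null_decoding_result(k = 2, nt = 25))
  ct <- perm_test_condition_diff(results, results, n_perm = 100, seed = 2)
  expect_null(ct$clusters)   # identical accuracies -> t = 0 everywhere
})

test_that("condition-difference test detects a planted late advantage", {
  set.seed(43)
  res_a <- list(); res_b <- list()
  for (p in 1:8) {
    a <- null_decoding_result(k = 2, n_ex = 40, nt = 30)
    b <- null_decoding_result(k = 2, n_ex = 40, nt = 30)
    for (tp in 15:25) {
      fix <- sample(40, 20)
      a$pred[fix, tp] <- a$true[fix]
    }
    a$accuracy <- colMeans(a$pred == a$true)
    res_a[[p]] <- a; res_b[[p]] <- b
  }
  ct <- perm_test_condition_diff(res_a, res_b, n_perm = 300, seed = 7)
  expect_true(has_significant_cluster(ct, sign = "pos"))
  expect_false(has_significant_cluster(ct, sign = "neg"))
})

test_that("group-difference test handles degenerate and planted cases", {
  times <- seq(0, by = 100, length.out = 20)
  # all participants identical -> no clusters
  acc <- matrix(0.6, 10, 20)
  ct <- perm_test_group_diff(acc, rep(c("hi", "lo"), each = 5),
                             n_perm = 50, times = times, seed = 1)
  expect_null(ct$clusters)
  # planted group difference
  set.seed(44)
  acc <- matrix(rnorm(200, 0.5, 0.05), 10, 20)
  acc[1:5, 8:14] <- acc[1:5, 8:14] + 0.25
  ct2 <- perm_test_group_diff(acc, rep(c("hi", "lo"), each = 5),
                              n_perm = 300, times = times, seed = 2)
  expect_true(has_significant_cluster(ct2))
  expect_error(perm_test_group_diff(acc, rep("hi", 10), times = times),
               "2 groups")
})

test_that("rho-to-t transform matches the closed form", {
  expect_equal(rho_to_t(0, 25), 0)
  expect_equal(rho_to_t(0.31, 40), 0.31 * sqrt(38 / (1 - 0.31^2)))
  expect_equal(rho_to_t(0.31, 40), 2.01, tolerance = 0.005)
  expect_warning(t1 <- rho_to_t(1, 10), "capped")
  expect_true(is.finite(t1))
})

test_that("correlation-timecourse clustering recovers a planted coupling", {
  set.seed(45)
  P <- 20; Tn <- 25
  y <- rnorm(P)
  x <- matrix(rnorm(P * Tn, 0, 1), P, Tn)
  x[, 10:16] <- x[, 10:16] + 2 * y    # strong coupling in 10..16
  ct <- corr_cluster_timecourse(x, y, n_perm = 300,
                                times = seq_len(Tn) * 100, seed = 3)
  expect_true(has_significant_cluster(ct, sign = "pos"))
  best <- ct$clusters[which.max(ct$clusters$mass), ]
  expect_true(best$start >= 9 && best$end <= 17)
})

test_that("2-D rank-matched TF test flags a planted frequency band", {
  set.seed(46)
  P <- 8; F <- 6; Tn <- 12
  results <- lapply(1:P, function(p) {
    pred <- array(sample.int(2, 30 * F * Tn, replace = TRUE),
                  c(30, F, Tn))
    true <- rep_len(1:2, 30)
    for (fi in 3:4) for (tp in 4:9) {
      fix <- sample(30, 16)
      pred[fix, fi, tp] <- true[fix]
    }
    acc <- apply(array(pred == true, dim(pred)), c(2, 3), mean)
    structure(list(accuracy = acc, freqs = seq(4, 24, length.out = F),
                   times = seq(0, by = 250, length.out = Tn),
                   pred = pred, true = true, block = rep(1, 30),
                   chance = 0.5), class = "tf_decoding_result")
  })
  ct <- perm_test_tf_vs_chance(results, chance = 0.5, n_perm = 200,
                               seed = 4)
  expect_false(is.null(ct$clusters))
  expect_true(any(ct$clusters$significant & ct$clusters$rank == 1))
})
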