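test_that("simulation is bit-identical given (config, participant)", {
  cfg <- small_cfg()
  a <- simulate_participant(cfg, 1)
  b <- simulate_participant(cfg, 1)
  expect_identical(a$epochs$data, b$epochs$data)
  expect_identical(a$truth, b$truth)
  c <- simulate_participant(cfg, 2)
  expect_false(identical(a$epochs$data, c$epochs$data))
})

test_that("trial structure matches the design", {
  cfg <- small_cfg()
  e <- simulate_participant(cfg, 1)$epochs
  tab <- table(e$trial_table$condition)
  expect_equal(unname(tab[["Think"]]), cfg$n_items_tnt * cfg$n_reps)
  expect_equal(unname(tab[["NoThink"]]), cfg$n_items_tnt * cfg$n_reps)
  expect_equal(unname(tab[["PerceptualBaseline"]]),
               cfg$n_items_pb * cfg$n_reps)
  # every item repeated n_reps times
  expect_true(all(table(e$trial_table$item_id) == cfg$n_reps))
  # the default config reproduces the full design: 300 trials
  full <- sim_config()
  expect_equal(2 * full$n_items_tnt * full$n_reps +
                 full$n_items_pb * full$n_reps, 300)
})

test_that("ground-truth patterns have the prescribed geometry", {
  cfg <- small_cfg()
  tr <- simulate_participant(cfg, 1)$truth
  m <- load_montage()
  occ <- m$region == "occipital"
  conc <- colSums(tr$cue_patterns[occ, ]^2) / colSums(tr$cue_patterns^2)
  expect_true(all(conc >= 0.7))
  # per-item strengths in [0.6, 1.4], linearly independent across items
  norms <- sqrt(colSums(tr$scene_patterns^2))
  expect_true(all(norms >= 0.6 & norms <= 1.4))
  expect_gt(sd(norms), 0)
  expect_equal(qr(tr$cue_patterns)$rank, ncol(tr$cue_patterns))
  expect_equal(qr(tr$scene_patterns)$rank, ncol(tr$scene_patterns))
  expect_true(tr$suppression >= 0 && tr$suppression <= 1)
})

test_that("zero-amplitude config yields pure stationary noise", {
  cfg <- small_cfg(cue_pattern_amp = 0, scene_pattern_amp = 0,
                   cond_theta_amp = 0, alpha_base_amp = 0)
  e <- simulate_participant(cfg, 1)$epochs
  expect_equal(sd(e$data), cfg$noise_sd, tolerance = 0.05)
  # no condition difference in variance between early and late windows
  late <- time_window_idx(e$times, c(500, 3000))
  early <- time_window_idx(e$times, c(-500, 0))
  expect_equal(sd(e$data[, , late]), sd(e$data[, , early]),
               tolerance = 0.05)
})

test_that("scene pattern present in Think, absent in Perceptual Baseline", {
  # low noise so the projection energy isolates the planted component
  cfg <- small_cfg(noise_sd = 0.5, alpha_base_amp = 0, cue_pattern_amp = 0)
  sim <- simulate_participant(cfg, 1)
  e <- sim$epochs; tr <- sim$truth
  late <- time_window_idx(e$times, c(500, 3000))
  # project trials onto their own item's scene pattern; oscillation makes
  # the mean zero, so compare projected energy against other conditions
  proj_energy <- function(cond) {
    idx <- which(e$trial_table$condition == cond)
    mean(vapply(idx, function(i) {
      pat <- tr$scene_patterns[, e$trial_table$item_id[i]]
      mean((pat %*% e$data[i, , late])^2)
    }, numeric(1)))
  }
  expect_gt(proj_energy("Think"), 2 * proj_energy("PerceptualBaseline"))
})

test_that("epoch windows that cannot hold the signal masks are rejected", {
  expect_error(sim_config(epoch_window = c(-200, 3500)), "epoch_window")
  expect_error(sim_config(epoch_window = c(-1000, 2000)), "epoch_window")
  expect_error(sim_config(suppression_factor = 1.4), "suppression_factor")
})

test_that("behavioral generator hits the target forgetting effect size", {
  # dz = 0 -> no Baseline-minus-NoThink Detail effect on average
  cfg0 <- small_cfg(forgetting_dz = 0)
  diffs <- replicate(100, {
    cfg0$seed <- derive_seed(cfg0$seed, 1)
    truths <- lapply(1:10, function(p) list(participant_id = p,
                                            suppression = runif(1, 0.6, 1)))
    b <- simulate_behavior(truths, cfg0)
    mean(b$detail[b$condition == "Baseline"]) -
      mean(b$detail[b$condition == "NoThink"])
  })
  expect_lt(abs(mean(diffs)), 0.1)

  # dz = 0.34 at n = 40: recovered dz within +/-0.15 over 200 replicates
  cfg <- small_cfg(forgetting_dz = 0.34)
  dzs <- replicate(200, {
    cfg$seed <- derive_seed(cfg$seed, 1)
    truths <- lapply(1:40, function(p) list(
      participant_id = p,
      suppression = min(max(rnorm(1, cfg$suppression_factor, 0.1), 0), 1)))
    b <- simulate_behavior(truths, cfg)
    bl <- b$detail[b$condition == "Baseline"]
    nt <- b$detail[b$condition == "NoThink"]
    paired_t_dz(bl, nt)$effect_size
  })
  expect_lt(abs(mean(dzs) - 0.34), 0.15)
})

test_that("Detail deficit increases with true suppression strength", {
  cfg <- small_cfg(forgetting_dz = 0.34)
  s_all <- c(); d_all <- c()
  for (r in 1:50) {
    cfg$seed <- derive_seed(cfg$seed, 1)
    s <- runif(20, 0, 1)
    truths <- lapply(1:20, function(p) list(participant_id = p,
                                            suppression = s[p]))
    b <- simulate_behavior(truths, cfg)
    d <- b$detail[b$condition == "Baseline"] -
      b$detail[b$condition == "NoThink"]
    s_all <- c(s_all, s); d_all <- c(d_all, d)
  }
  expect_gt(cor(s_all, d_all), 0.3)
})

test_that("subjective ratings track the embedded pattern geometry", {
  cfg <- small_cfg(n_items_tnt = 12)
  truth <- simulate_participant(cfg, 1)$truth

  # noise-free raters reproduce the generating distances up to rank
  cfg0 <- cfg; cfg0$rater_noise_sd <- 0
  r0 <- simulate_subjective_ratings(truth, cfg0)
  expect_equal(dim(r0$conceptual), c(cfg$n_raters, 12, 12))
  avg <- average_subjective_rdm(r0$conceptual)
  items <- rownames(avg)
  D <- as.matrix(dist(t(truth$scene_patterns[, items])))
  lt <- lower.tri(D)
  expect_equal(cor(avg[lt], D[lt], method = "spearman"), 1)
  # 12 items -> 66 informative pairs
  expect_equal(sum(lt), 66)

  # default rater noise, 22 raters: averaged RDM still rho > 0.5
  r1 <- simulate_subjective_ratings(truth, cfg)
  avg1 <- average_subjective_rdm(r1$conceptual)
  expect_gt(cor(avg1[lt], D[lt], method = "spearman"), 0.5)
  # perceptual ratings track cue distances, not scene distances
  avgp <- average_subjective_rdm(r1$perceptual)
  Dc <- as.matrix(dist(t(truth$cue_patterns[, items])))
  expect_gt(cor(avgp[lt], Dc[lt], method = "spearman"),
            cor(avgp[lt], D[lt], method = "spearman"))
})
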