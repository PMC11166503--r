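test_that("frequency grid is geometric with 22 points from 2.8 to 30 Hz", {
  f <- morlet_freqs()
  expect_length(f, 22)
  expect_equal(f[1], 2.8)
  expect_equal(f[22], 30)
  expect_equal(diff(log(f)), rep(diff(log(f))[1], 21))
})

test_that("cycle counts ramp linearly from 3 to 7", {
  expect_equal(morlet_cycles(2.8), 3)
  expect_equal(morlet_cycles(30), 7)
  expect_equal(morlet_cycles(16.4), 5)
})

test_that("Morlet power peaks at the grid frequency nearest the input", {
  sfreq <- 250
  times <- seq(-1000, 2000, by = 1000 / sfreq)
  nt <- length(times)
  data <- array(0, c(2, 1, nt))
  data[1, 1, ] <- sin(2 * pi * 10 * times / 1000)
  data[2, 1, ] <- sin(2 * pi * 5 * times / 1000)
  x <- epoch_set(data, times, sfreq, "Oz",
                 data.frame(condition = rep("Think", 2),
                            item_id = c("a", "b"), participant_id = 1))
  tfr <- morlet_tfr(x)
  prof1 <- apply(tfr$power[1, 1, , ], 1, mean, na.rm = TRUE)
  prof2 <- apply(tfr$power[2, 1, , ], 1, mean, na.rm = TRUE)
  f <- tfr$freqs
  expect_equal(which.max(prof1), which.min(abs(f - 10)))
  expect_equal(which.max(prof2), which.min(abs(f - 5)))
  # edge samples are flagged invalid, more of them at low frequencies
  expect_true(anyNA(tfr$power[1, 1, 1, ]))
  na_low <- sum(is.na(tfr$power[1, 1, 1, ]))
  na_high <- sum(is.na(tfr$power[1, 1, 22, ]))
  expect_gt(na_low, na_high)
})

test_that("dB baselining follows 10*log10(power / baseline mean)", {
  times <- seq(-600, 1000, by = 10)
  nt <- length(times)
  base <- time_window_idx(times, c(-500, -200))
  power <- array(2, c(1, 1, 1, nt))       # constant = baseline -> 0 dB
  power[1, 1, 1, times >= 0 & times < 200] <- 20      # 10x -> +10 dB
  power[1, 1, 1, times >= 200 & times < 400] <- 1     # half -> -3.0103 dB
  tfr <- structure(list(power = power, freqs = 10, cycles = 5,
                        times = times, sfreq = 100, channel_names = "Cz",
                        trial_table = NULL, baseline_state = "raw"),
                   class = "tfr_set")
  db <- db_baseline(tfr, c(-500, -200))
  expect_equal(db$baseline_state, "dB")
  expect_equal(db$power[1, 1, 1, base], rep(0, length(base)))
  expect_equal(unique(db$power[1, 1, 1, times >= 0 & times < 200]), 10)
  expect_equal(unique(db$power[1, 1, 1, times >= 200 & times < 400]),
               10 * log10(0.5), tolerance = 1e-6)
  # double baselining is rejected, as is nonpositive baseline power
  expect_error(db_baseline(db), "already")
  tfr$power[] <- 0
  expect_error(db_baseline(tfr, c(-500, -200)), "baseline")
})

test_that("doubling the amplitude quadruples raw power (+6.02 dB)", {
  set.seed(3)
  e <- tiny_epochs(n = 2, nch = 2, nt = 500)
  e$data <- e$data + array(rnorm(length(e$data)), dim(e$data))
  e2 <- e; e2$data <- 2 * e$data
  t1 <- morlet_tfr(e, freqs = c(8, 15))
  t2 <- morlet_tfr(e2, freqs = c(8, 15))
  ratio <- t2$power / t1$power
  expect_equal(mean(ratio, na.rm = TRUE), 4, tolerance = 1e-10)
  expect_equal(10 * log10(mean(ratio, na.rm = TRUE)), 6.02, tolerance = 0.01)
})

test_that("band_power selects the right bins and windows", {
  freqs <- morlet_freqs()
  times <- seq(-500, 1000, by = 10)
  power <- array(7, c(3, 2, length(freqs), length(times)))
  tfr <- structure(list(power = power, freqs = freqs, cycles = NULL,
                        times = times, sfreq = 100,
                        channel_names = c("a", "b"), trial_table = NULL,
                        baseline_state = "raw"), class = "tfr_set")
  bp <- band_power(tfr, c(4, 8), c(200, 400))
  expect_equal(dim(bp), c(3, 2))
  expect_true(all(bp == 7))           # uniform field returns itself
  expect_error(band_power(tfr, c(40, 50), c(200, 400)), "band")
  # theta summary = mean over bins with centres in 4-8 Hz
  in_theta <- which(freqs >= 4 & freqs <= 8)
  power2 <- power
  power2[, , in_theta, ] <- 1
  tfr$power <- power2
  expect_true(all(band_power(tfr, c(4, 8), c(200, 400)) == 1))
})

test_that("planted theta burst shows as a frontocentral NT > PB contrast", {
  cfg <- small_cfg(cue_pattern_amp = 0, scene_pattern_amp = 0,
                   alpha_base_amp = 0, cond_theta_amp = 8,
                   epoch_window = c(-1000, 3000))
  e <- simulate_participant(cfg, 1)$epochs
  m <- load_montage()
  fc <- which(m$region == "frontocentral")
  keep_ch <- c(fc, which(m$region == "occipital"))
  e$data <- e$data[, keep_ch, , drop = FALSE]
  e$channel_names <- e$channel_names[keep_ch]
  sub <- select_trials(e, e$trial_table$condition %in%
                         c("NoThink", "PerceptualBaseline"))
  tfr <- db_baseline(morlet_tfr(sub, decim = 2))
  bp <- band_power(tfr, c(4, 8), c(200, 400))
  nt <- sub$trial_table$condition == "NoThink"
  isfc <- seq_along(keep_ch) <= length(fc)
  contrast_fc <- mean(bp[nt, isfc]) - mean(bp[!nt, isfc])
  contrast_occ <- mean(bp[nt, !isfc]) - mean(bp[!nt, !isfc])
  expect_gt(contrast_fc, 1)         # dB increase at frontocentral sites
  expect_gt(contrast_fc, contrast_occ + 1)
})

test_that("ERP component amplitudes average cluster, window and trials", {
  m <- load_montage()
  times <- seq(-500, 996, by = 4)
  nch <- nrow(m)
  data <- array(0, c(4, nch, length(times)))
  tt <- data.frame(condition = rep(c("NoThink", "PerceptualBaseline"), 2),
                   item_id = "x", participant_id = 1)
  e <- epoch_set(data, times, 250, m$channel, tt, montage = m)
  spec <- erp_component_spec("N450")
  # zero signal -> 0; constant 2 uV over cluster/window -> 2
  expect_equal(erp_amplitude(e, spec)$amplitude, c(0, 0))
  ci <- match(spec$electrodes, m$channel)
  ti <- time_window_idx(times, spec$window)
  e$data[, ci, ti] <- 2
  expect_equal(erp_amplitude(e, spec)$amplitude, c(2, 2))
  # planted frontocentral negativity in No-Think only
  e$data[tt$condition == "NoThink", ci, ti] <- -3
  amp <- erp_amplitude(e, spec)
  expect_lt(amp$amplitude[amp$condition == "NoThink"],
            amp$amplitude[amp$condition == "PerceptualBaseline"])
  expect_error(erp_amplitude(e, erp_component_spec("N450",
                                                   electrodes = "Nope")),
               "missing")
})
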