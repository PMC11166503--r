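#' Configuration of the synthetic Think/No-Think EEG experiment
#'
#' Defaults reproduce the study design the pipeline targets: 12 Think and
#' 12 No-Think items and 6 Perceptual Baseline items, 10 repetitions each
#' (300 trials), epochs -1000..3500 ms at 250 Hz over the packaged
#' 61-channel montage, with an independent 22-rater sample for subjective
#' dissimilarity ratings and a population suppression-induced forgetting
#' effect of dz = 0.34 on the Detail recall score.
#'
#' Signal structure per trial (all on top of spatially smoothed 1/f noise):
#' an item-specific occipital theta-band (6 Hz) "cue" pattern over
#' 0-500 ms in every condition; an item-specific distributed alpha-band
#' (10.5 Hz) "scene" pattern over 500-3000 ms with gain 1 in Think,
#' `1 - suppression` in No-Think and 0 in Perceptual Baseline; a
#' frontocentral theta burst over 200-400 ms in No-Think only; and ongoing
#' posterior alpha over 500-3000 ms whose power is reduced by `alpha_mod`
#' in No-Think.
#'
#' @param n_participants number of simulated participants.
#' @param n_items_tnt items per Think and per No-Think condition.
#' @param n_items_pb Perceptual Baseline items.
#' @param n_reps repetitions per item.
#' @param sfreq sampling rate (Hz).
#' @param epoch_window epoch limits in ms; must span at least -500..3000 so
#'   every signal mask and the pre-stimulus baseline fit.
#' @param cue_pattern_amp amplitude (uV) of the item-specific occipital cue
#'   pattern.
#' @param scene_pattern_amp amplitude (uV) of the item-specific distributed
#'   scene pattern.
#' @param suppression_factor population mean of the per-participant
#'   suppression strength in `[0, 1]`; the No-Think scene-pattern gain is
#'   `1 - s`, so `s = 1` abolishes late item information in No-Think.
#' @param cond_theta_amp amplitude (uV) of the No-Think frontocentral
#'   200-400 ms theta burst.
#' @param alpha_mod fractional reduction of late ongoing alpha power in
#'   No-Think (0 = none).
#' @param alpha_base_amp amplitude (uV) of ongoing posterior alpha common
#'   to all conditions over 500-3000 ms.
#' @param noise_sd standard deviation (uV) of the 1/f background noise.
#' @param noise_exponent spectral slope of the background noise.
#' @param n_raters raters in the subjective-rating sample.
#' @param rater_noise_sd rating noise on the 1-9 scale.
#' @param forgetting_dz target population effect size (Cohen's dz) of the
#'   Baseline - No-Think Detail recall difference.
#' @param trial_jitter if `TRUE`, drop a small random number of trials per
#'   condition to emulate artifact-rejection counts; default off so trial
#'   counts are exact.
#' @param seed master seed; together with the participant index it fully
#'   determines every simulated array.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_participants = 40,
                       n_items_tnt = 12, n_items_pb = 6, n_reps = 10,
                       sfreq = 250, epoch_window = c(-1000, 3500),
                       cue_pattern_amp = 8, scene_pattern_amp = 6,
                       suppression_factor = 0.85,
                       cond_theta_amp = 4, alpha_mod = 0.3,
                       alpha_base_amp = 2,
                       noise_sd = 2, noise_exponent = 1,
                       n_raters = 22, rater_noise_sd = 1,
                       forgetting_dz = 0.34,
                       trial_jitter = FALSE, seed = 1) {
  cfg <- list(n_participants = n_participants, n_items_tnt = n_items_tnt,
              n_items_pb = n_items_pb, n_reps = n_reps, sfreq = sfreq,
              epoch_window = epoch_window,
              cue_pattern_amp = cue_pattern_amp,
              scene_pattern_amp = scene_pattern_amp,
              suppression_factor = suppression_factor,
              cond_theta_amp = cond_theta_amp, alpha_mod = alpha_mod,
              alpha_base_amp = alpha_base_amp,
              noise_sd = noise_sd, noise_exponent = noise_exponent,
              n_raters = n_raters, rater_noise_sd = rater_noise_sd,
              forgetting_dz = forgetting_dz,
              trial_jitter = trial_jitter, seed = seed)
  .assert(all(c(cue_pattern_amp, scene_pattern_amp, cond_theta_amp,
                alpha_base_amp, noise_sd) >= 0), "amplitudes must be >= 0")
  .assert(suppression_factor >= 0 && suppression_factor <= 1,
          "suppression_factor must be in [0, 1]")
  .assert(alpha_mod >= 0 && alpha_mod <= 1, "alpha_mod must be in [0, 1]")
  .assert(epoch_window[1] <= -500 && epoch_window[2] >= 3000,
          "epoch_window must span at least -500..3000 ms to contain the signal masks")
  class(cfg) <- "sim_config"
  cfg
}

# raised-cosine (Hann) envelope over a half-open ms window
.hann_env <- function(times, window) {
  env <- numeric(length(times))
  idx <- time_window_idx(times, window)
  if (length(idx)) {
    u <- (times[idx] - window[1]) / (window[2] - window[1])
    env[idx] <- 0.5 - 0.5 * cos(2 * pi * u)
  }
  env
}

# 1/f^expo noise: white noise shaped in the frequency domain (on a padded
# composite-length grid so the FFT stays fast), then mixed across the k
# nearest channels and scaled to sd = noise_sd
.pink_noise <- function(nt, nch, sfreq, expo, noise_sd, mix) {
  nfft <- stats::nextn(nt)
  w <- matrix(stats::rnorm(nfft * nch), nfft, nch)
  if (expo > 0) {
    fidx <- c(1, pmin(seq_len(nfft - 1), nfft - seq_len(nfft - 1)))
    f <- fidx * sfreq / nfft
    f[1] <- f[2]
    g <- f^(-expo / 2)
    w <- Re(stats::mvfft(stats::mvfft(w) * g, inverse = TRUE)) / nfft
  }
  w <- w[seq_len(nt), , drop = FALSE] %*% mix
  w * (noise_sd / stats::sd(w))
}

#' Simulate one participant's epoched EEG with known ground truth
#'
#' @param config a [sim_config()].
#' @param participant_id positive integer; `(config$seed, participant_id)`
#'   fully determine the output.
#' @param montage montage to simulate on (default: packaged 61-channel
#'   10-05 template).
#' @return List with `epochs` (an `epoch_set`) and `truth` (per-item cue and
#'   scene channel patterns, condition effect masks, and the participant's
#'   true suppression strength).
#' @export
simulate_participant <- function(config, participant_id, montage = NULL) {
  .assert(inherits(config, "sim_config"), "config must be a sim_config")
  if (is.null(montage)) montage <- load_montage()
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(config$seed, participant_id))

  ch <- montage$channel
  nch <- length(ch)
  region <- montage$region
  times <- seq(config$epoch_window[1], config$epoch_window[2],
               by = 1000 / config$sfreq)
  nt <- length(times)
  tsec <- times / 1000

  occ <- which(region == "occipital")
  par_ <- which(region == "parietal")
  fc <- which(region == "frontocentral")
  scene_w <- c(occipital = 1, parietal = 1, frontocentral = 0.5,
               frontal = 0.8, central = 0.5, temporal = 0.3)[region]

  # item patterns are drawn random within their scalp region, then passed
  # through the same volume-conduction kernel as the noise so they are
  # spatially smooth like real scalp fields (rough patterns would be
  # unphysical and would not survive spatial PCA)
  pos <- as.matrix(montage[, c("x", "y", "z")])
  Dm <- as.matrix(stats::dist(pos))
  K <- exp(-Dm^2 / (2 * 0.5^2))
  K <- sweep(K, 2, sqrt(colSums(K^2)), "/")
  mix <- 0.9 * K + 0.1 * diag(nch)

  items <- c(sprintf("T%02d", seq_len(config$n_items_tnt)),
             sprintf("N%02d", seq_len(config$n_items_tnt)),
             sprintf("P%02d", seq_len(config$n_items_pb)))
  cue_pat <- matrix(0, nch, length(items), dimnames = list(ch, items))
  scene_pat <- matrix(0, nch, length(items), dimnames = list(ch, items))
  # evoked oscillations are phase-locked with a common phase across items:
  # item identity is carried by the spatial pattern alone, so pairwise
  # pattern distances are preserved at every timepoint
  cue_phase <- rep(stats::runif(1, 0, 2 * pi), length(items))
  scene_phase <- rep(stats::runif(1, 0, 2 * pi), length(items))
  # per-item pattern strengths: without them random high-dimensional
  # patterns are nearly equidistant and the item geometry carries no
  # variance for RSA to recover
  cue_strength <- stats::runif(length(items), 0.6, 1.4)
  scene_strength <- stats::runif(length(items), 0.6, 1.4)
  for (k in seq_along(items)) {
    v <- numeric(nch)
    v[occ] <- stats::rnorm(length(occ))
    v[par_] <- stats::rnorm(length(par_)) * 0.4
    v <- as.vector(K %*% v)
    # re-impose the occipital concentration after smoothing
    e_occ <- sum(v[occ]^2); e_rest <- sum(v[-occ]^2)
    v[occ] <- v[occ] * sqrt(0.75 / e_occ)
    v[-occ] <- v[-occ] * sqrt(0.25 / e_rest)
    cue_pat[, k] <- v * cue_strength[k]
    w <- as.vector(K %*% (stats::rnorm(nch) * scene_w))
    scene_pat[, k] <- w / sqrt(sum(w^2)) * scene_strength[k]
  }
  suppression <- min(max(stats::rnorm(1, config$suppression_factor, 0.1), 0), 1)

  cond_pat <- as.numeric(region == "frontocentral")
  cond_pat <- cond_pat / sqrt(sum(cond_pat^2))
  alpha_prof <- as.numeric(region %in% c("parietal", "occipital"))
  alpha_prof <- alpha_prof / sqrt(sum(alpha_prof^2))

  env_cue <- .hann_env(times, c(0, 500))
  env_scene <- .hann_env(times, c(500, 3000))
  env_burst <- .hann_env(times, c(200, 400))

  tt <- data.frame(
    condition = rep(c("Think", "NoThink", "PerceptualBaseline"),
                    times = c(config$n_items_tnt, config$n_items_tnt,
                              config$n_items_pb) * config$n_reps),
    item_id = c(rep(items[seq_len(config$n_items_tnt)], each = config$n_reps),
                rep(items[config$n_items_tnt + seq_len(config$n_items_tnt)],
                    each = config$n_reps),
                rep(items[2 * config$n_items_tnt + seq_len(config$n_items_pb)],
                    each = config$n_reps)),
    stringsAsFactors = FALSE)
  tt <- tt[sample(nrow(tt)), , drop = FALSE]
  rownames(tt) <- NULL
  tt$participant_id <- participant_id

  if (config$trial_jitter) {
    drop_n <- stats::rbinom(1, nrow(tt), 0.05)
    if (drop_n > 0 && drop_n < nrow(tt)) {
      tt <- tt[-sample(nrow(tt), drop_n), , drop = FALSE]
      rownames(tt) <- NULL
    }
  }

  data <- array(0, c(nrow(tt), nch, nt))
  f_theta <- 6; f_alpha <- 10.5; f_bg_alpha <- 10
  for (tr in seq_len(nrow(tt))) {
    x <- t(.pink_noise(nt, nch, config$sfreq, config$noise_exponent,
                       config$noise_sd, mix))          # channels x time
    it <- match(tt$item_id[tr], items)
    cond <- tt$condition[tr]
    # evoked components carry an oscillatory component plus a mean
    # deflection, as real event-related responses do
    x <- x + config$cue_pattern_amp *
      (cue_pat[, it] %o% (env_cue * (cos(2 * pi * f_theta * tsec +
                                         cue_phase[it]) + 1)))
    gain <- switch(cond, Think = 1, NoThink = 1 - suppression,
                   PerceptualBaseline = 0)
    if (gain != 0 && config$scene_pattern_amp > 0) {
      x <- x + gain * config$scene_pattern_amp *
        (scene_pat[, it] %o% (env_scene * (cos(2 * pi * f_alpha * tsec +
                                               scene_phase[it]) + 1)))
    }
    if (cond == "NoThink" && config$cond_theta_amp > 0) {
      # negative mean deflection: an N450-like frontocentral negativity
      # with a theta-band carrier
      x <- x + config$cond_theta_amp *
        (cond_pat %o% (env_burst * (cos(2 * pi * f_theta * tsec) - 0.6)))
    }
    if (config$alpha_base_amp > 0) {
      a_amp <- config$alpha_base_amp *
        if (cond == "NoThink") sqrt(1 - config$alpha_mod) else 1
      ph <- stats::runif(1, 0, 2 * pi)
      x <- x + a_amp *
        (alpha_prof %o% (env_scene * cos(2 * pi * f_bg_alpha * tsec + ph)))
    }
    data[tr, , ] <- x
  }

  epochs <- epoch_set(data, times, config$sfreq, ch, tt, montage = montage)
  truth <- list(participant_id = participant_id,
                cue_patterns = cue_pat, scene_patterns = scene_pat,
                suppression = suppression,
                masks = list(cue = c(0, 500), scene = c(500, 3000),
                             cond_theta = c(200, 400)),
                items = items)
  list(epochs = epochs, truth = truth)
}

#' Simulate behavioral recall scores for a set of participants
#'
#' Detail recall in No-Think is depressed relative to Baseline by an amount
#' that increases linearly with the participant's true suppression
#' strength, with the intercept solved so the population Baseline -
#' No-Think effect size equals `config$forgetting_dz`:
#' `deficit = a + b (s - s_bar) + e`, `a = dz * sqrt(b^2 Var(s) + sd_e^2)`.
#'
#' @param truths list of ground-truth objects from [simulate_participant()];
#'   at least 2.
#' @param config the [sim_config()] used to generate them.
#' @return data.frame `participant, condition, identification, gist,
#'   detail` with conditions Think / NoThink / Baseline.
#' @export
simulate_behavior <- function(truths, config) {
  .assert(length(truths) >= 2, "need at least 2 participants")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(config$seed, 90001))
  s <- vapply(truths, function(t) t$suppression, numeric(1))
  ids <- vapply(truths, function(t) t$participant_id, numeric(1))
  n <- length(s)
  b <- 2; sd_e <- 1; var_s <- 0.1^2
  a <- config$forgetting_dz * sqrt(b^2 * var_s + sd_e^2)
  deficit <- a + b * (s - config$suppression_factor) + stats::rnorm(n, 0, sd_e)

  det_bl <- pmax(stats::rnorm(n, 6, 1.2), 0)
  det_nt <- pmax(det_bl - deficit, 0)
  det_t <- pmax(det_bl + stats::rnorm(n, 0.5, 0.8), 0)
  id_bl <- pmin(pmax(stats::rnorm(n, 0.85, 0.08), 0), 1)
  id_nt <- pmin(pmax(id_bl - 0.03 * deficit, 0), 1)
  id_t <- pmin(pmax(id_bl + 0.02, 0), 1)
  gi_bl <- pmin(pmax(stats::rnorm(n, 0.7, 0.1), 0), 1)
  gi_nt <- pmin(pmax(gi_bl - 0.02 * deficit, 0), 1)
  gi_t <- pmin(pmax(gi_bl + 0.02, 0), 1)

  out <- rbind(
    data.frame(participant = ids, condition = "Think",
               identification = id_t, gist = gi_t, detail = det_t),
    data.frame(participant = ids, condition = "NoThink",
               identification = id_nt, gist = gi_nt, detail = det_nt),
    data.frame(participant = ids, condition = "Baseline",
               identification = id_bl, gist = gi_bl, detail = det_bl))
  rownames(out) <- NULL
  out
}

#' Simulate per-rater subjective (dis)similarity ratings
#'
#' Raters score every item pair on a 1 (extremely dissimilar) to
#' 9 (extremely similar) scale. Conceptual ratings are a noisy linear
#' transform of the scene-pattern distances of the ground truth, perceptual
#' ratings of the cue-pattern distances, so the subjective geometry is
#' correlated with the geometry embedded in the EEG.
#'
#' @param truth a ground truth from [simulate_participant()].
#' @param config the [sim_config()].
#' @param items item ids to rate (default: the Think items).
#' @return List of two `raters x items x items` arrays, `perceptual` and
#'   `conceptual`, symmetric with `NA` diagonals.
#' @export
simulate_subjective_ratings <- function(truth, config, items = NULL) {
  .assert(config$n_raters >= 2, "need n_raters >= 2")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(config$seed, 90002, truth$participant_id))
  if (is.null(items)) items <- grep("^T", truth$items, value = TRUE)
  one <- function(pat) {
    D <- as.matrix(stats::dist(t(pat[, items, drop = FALSE])))
    off <- D[upper.tri(D)]
    Dn <- (D - min(off)) / max(max(off) - min(off), .Machine$double.eps)
    sim_true <- 9 - 8 * Dn
    out <- array(NA_real_, c(config$n_raters, length(items), length(items)),
                 dimnames = list(NULL, items, items))
    ut <- which(upper.tri(D), arr.ind = TRUE)
    for (r in seq_len(config$n_raters)) {
      m <- matrix(NA_real_, length(items), length(items))
      vals <- pmin(pmax(sim_true[ut] +
                        stats::rnorm(nrow(ut), 0, config$rater_noise_sd),
                        1), 9)
      m[ut] <- vals
      m[ut[, c(2, 1)]] <- vals
      out[r, , ] <- m
    }
    out
  }
  list(perceptual = one(truth$cue_patterns),
       conceptual = one(truth$scene_patterns))
}

#' Simulate a full study (EEG, behavior, ratings)
#'
#' @param config a [sim_config()].
#' @param montage optional montage (default packaged).
#' @return List with `epochs` (list per participant), `truths`, `behavior`
#'   and `ratings` (from the first participant's geometry, as the rating
#'   sample is independent of the EEG sample).
#' @export
simulate_study <- function(config, montage = NULL) {
  if (is.null(montage)) montage <- load_montage()
  sims <- lapply(seq_len(config$n_participants), function(p) {
    simulate_participant(config, p, montage = montage)
  })
  truths <- lapply(sims, `[[`, "truth")
  list(epochs = lapply(sims, `[[`, "epochs"),
       truths = truths,
       behavior = simulate_behavior(truths, config),
       ratings = simulate_subjective_ratings(truths[[1]], config))
}
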