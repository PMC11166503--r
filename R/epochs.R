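#' Construct an epoched EEG container
#'
#' The central data container: a trials x channels x timepoints array of
#' voltages (uV) with a uniform millisecond time axis (0 = cue onset), the
#' montage, and a per-trial table carrying condition and item labels.
#'
#' @param data numeric array `trials x channels x timepoints` (uV).
#' @param times numeric vector of sample times in ms, strictly increasing
#'   and uniform at `1000 / sfreq`.
#' @param sfreq sampling frequency in Hz.
#' @param channel_names character vector, unique, length = dim 2.
#' @param trial_table data.frame with one row per trial and at least
#'   columns `condition` (one of `"Think"`, `"NoThink"`,
#'   `"PerceptualBaseline"`), `item_id` and `participant_id`.
#' @param montage optional [load_montage()] object (may cover a superset of
#'   `channel_names`).
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, times, sfreq, channel_names, trial_table,
                      montage = NULL) {
  .assert(length(dim(data)) == 3, "data must be trials x channels x time")
  .assert(dim(data)[2] == length(channel_names), "channel axis mismatch")
  .assert(dim(data)[3] == length(times), "time axis mismatch")
  .assert(!anyDuplicated(channel_names), "duplicate channel names")
  dt <- diff(times)
  .assert(all(dt > 0), "times must be strictly increasing")
  .assert(max(abs(dt - 1000 / sfreq)) < 1e-6,
          "times must be uniform at 1/sfreq")
  .assert(is.data.frame(trial_table) && nrow(trial_table) == dim(data)[1],
          "trial_table must have one row per trial")
  .assert(all(c("condition", "item_id") %in% names(trial_table)),
          "trial_table needs condition and item_id")
  .assert(!anyNA(trial_table$condition), "every trial needs a condition")
  .assert(!anyNA(trial_table$item_id), "every trial needs an item_id")
  dimnames(data) <- list(NULL, channel_names, NULL)
  structure(list(data = data, times = as.numeric(times), sfreq = sfreq,
                 channel_names = channel_names,
                 trial_table = trial_table, montage = montage),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat("<epoch_set> ", dim(x$data)[1], " trials x ", dim(x$data)[2],
      " channels x ", dim(x$data)[3], " samples; ",
      x$times[1], "..", x$times[length(x$times)], " ms @ ", x$sfreq, " Hz\n",
      sep = "")
  print(table(x$trial_table$condition))
  invisible(x)
}

#' Number of trials
#' @param x an `epoch_set` or `feature_epochs`.
#' @return Integer trial count.
#' @export
n_trials <- function(x) dim(x$data)[1]

#' Subset trials of an epoch set
#' @param epochs an `epoch_set`.
#' @param idx integer or logical trial index.
#' @return An `epoch_set` restricted to the selected trials.
#' @export
select_trials <- function(epochs, idx) {
  epochs$data <- epochs$data[idx, , , drop = FALSE]
  epochs$trial_table <- epochs$trial_table[idx, , drop = FALSE]
  rownames(epochs$trial_table) <- NULL
  epochs
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean voltage over the baseline
#' window (half-open `[start, end)` ms).
#'
#' @param epochs an `epoch_set`.
#' @param window baseline window in ms, default `c(-500, 0)`.
#' @return The corrected `epoch_set`.
#' @export
baseline_correct <- function(epochs, window = c(-500, 0)) {
  idx <- time_window_idx(epochs$times, window)
  .assert(length(idx) > 0, "baseline window outside the epoch time axis")
  bl <- apply(epochs$data[, , idx, drop = FALSE], c(1, 2), mean)
  epochs$data <- epochs$data - array(bl, dim = dim(epochs$data))
  epochs
}

#' Reject trials containing large-amplitude artifacts
#'
#' Removes every trial whose absolute voltage exceeds `threshold` uV at any
#' channel or sample, mirroring a +/-100 uV peak-to-peak rejection pass on
#' already-cleaned data.
#'
#' @param epochs an `epoch_set`.
#' @param threshold positive amplitude bound in uV (default 100).
#' @return List with elements `epochs` (trials retained) and `log`
#'   (data.frame of removed trial index, condition and peak |uV|).
#' @export
reject_artifacts <- function(epochs, threshold = 100) {
  .assert(threshold > 0, "threshold must be positive")
  peaks <- apply(abs(epochs$data), 1, max)
  bad <- which(peaks > threshold)
  log <- data.frame(trial = bad,
                    condition = epochs$trial_table$condition[bad],
                    peak = peaks[bad])
  if (length(bad)) {
    kept <- epochs$trial_table$condition[-bad]
    lost <- setdiff(unique(epochs$trial_table$condition), unique(kept))
    if (length(lost)) {
      stop("artifact rejection removed every trial of condition: ",
           paste(lost, collapse = ", "), call. = FALSE)
    }
    epochs <- select_trials(epochs, -bad)
  }
  list(epochs = epochs, log = log)
}

#' Subsample one condition to match another's trial count
#'
#' Random without-replacement subsampling of `condition_a` down to the trial
#' count of `condition_b` (the paper's Think/No-Think vs Perceptual
#' Baseline matching); all other trials are kept untouched.
#'
#' @param epochs an `epoch_set`.
#' @param condition_a condition to subsample.
#' @param condition_b condition whose count is matched.
#' @param seed integer seed; the subset is deterministic given the seed.
#' @return An `epoch_set`.
#' @export
subsample_to_match <- function(epochs, condition_a, condition_b, seed = 1) {
  cond <- epochs$trial_table$condition
  .assert(condition_a %in% cond, paste("unknown condition:", condition_a))
  .assert(condition_b %in% cond, paste("unknown condition:", condition_b))
  ia <- which(cond == condition_a)
  nb <- sum(cond == condition_b)
  .assert(length(ia) >= nb, "condition_a has fewer trials than condition_b")
  if (length(ia) == nb) return(epochs)
  withr_seed <- derive_seed(seed, length(ia), nb)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(withr_seed)
  keep_a <- sort(sample(ia, nb))
  select_trials(epochs, sort(c(keep_a, which(cond != condition_a))))
}

#' Subsample a condition to a fixed trial count
#'
#' @param epochs an `epoch_set`.
#' @param condition condition label to thin.
#' @param n target trial count.
#' @param seed integer seed.
#' @return An `epoch_set`.
#' @export
subsample_trials <- function(epochs, condition, n, seed = 1) {
  idx <- which(epochs$trial_table$condition == condition)
  .assert(length(idx) >= n, "fewer trials than requested")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, n))
  keep <- sort(sample(idx, n))
  select_trials(epochs, sort(c(keep, setdiff(seq_len(n_trials(epochs)), idx))))
}

# save/restore the global RNG state so seeded helpers do not perturb
# the caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
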