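# shared fixtures, all generated in code

# a small epoch set built by hand: n trials, nch channels, -500..996 ms
# at 250 Hz, two conditions / four items
tiny_epochs <- function(n = 8, nch = 6, fill = 0, sfreq = 250,
                        t0 = -500, nt = 375) {
  times <- seq(t0, by = 1000 / sfreq, length.out = nt)
  data <- array(fill, c(n, nch, nt))
  tt <- data.frame(
    condition = rep(c("Think", "PerceptualBaseline"), length.out = n),
    item_id = rep(paste0("it", 1:4), length.out = n),
    participant_id = 1)
  epoch_set(data, times, sfreq, paste0("ch", seq_len(nch)), tt)
}

# scaled-down simulation config used across tests: 100 Hz, 6+6+4 items,
# 6 repetitions, default (strong) amplitudes unless overridden
small_cfg <- function(...) {
  defaults <- list(n_participants = 2, n_items_tnt = 6, n_items_pb = 4,
                   n_reps = 6, sfreq = 100, epoch_window = c(-500, 3000),
                   seed = 101)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# synthetic feature_epochs with k classes whose patterns separate at
# selected "timepoints" and are pure noise elsewhere
separable_features <- function(k = 4, reps = 9, p = 10, nt = 3,
                               signal_at = nt, amp = 4, seed = 1) {
  set.seed(seed)
  n <- k * reps
  pats <- matrix(rnorm(k * p), k, p) * amp
  data <- array(rnorm(n * p * nt), c(n, p, nt))
  for (t in signal_at) {
    data[, , t] <- data[, , t] + pats[rep(seq_len(k), each = reps), ]
  }
  structure(list(data = data, times = seq(0, by = 20, length.out = nt),
                 sfreq = 50,
                 trial_table = data.frame(
                   condition = "Think",
                   item_id = rep(paste0("it", seq_len(k)), each = reps))),
            class = "feature_epochs")
}

# hand-built decoding_result with random (null) classification records
null_decoding_result <- function(k = 2, n_ex = 40, nt = 40, times = NULL,
                                 n_blocks = 2) {
  times <- times %||% seq(0, by = 50, length.out = nt)
  pred <- matrix(sample.int(k, n_ex * nt, replace = TRUE), n_ex, nt)
  true <- rep_len(seq_len(k), n_ex)
  structure(list(accuracy = colMeans(pred == true), times = times,
                 pred = pred, true = true,
                 block = rep(seq_len(n_blocks), each = ceiling(n_ex / n_blocks))[seq_len(n_ex)],
                 chance = 1 / k, classes = paste0("c", seq_len(k))),
            class = "decoding_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
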