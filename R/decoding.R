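#' Spatial PCA feature reduction
#'
#' Fits a spatial PCA per participant on all trials and timepoints pooled
#' (channels as variables) and projects the data onto the leading
#' components, the standard dimensionality-reduction step before decoding.
#'
#' @param epochs an `epoch_set`.
#' @param n_components number of retained components (default 15).
#' @return A `feature_epochs`: `data` is `trials x components x time`;
#'   `rotation`, `center` and `var_explained` record the fit.
#' @export
pca_reduce <- function(epochs, n_components = 15) {
  d <- dim(epochs$data)
  .assert(d[2] >= n_components, "more components requested than channels")
  M <- matrix(aperm(epochs$data, c(1, 3, 2)), ncol = d[2])
  mu <- colMeans(M)
  Mc <- sweep(M, 2, mu)
  C <- crossprod(Mc) / (nrow(Mc) - 1)
  eig <- eigen(C, symmetric = TRUE)
  rank <- sum(eig$values > max(eig$values) * 1e-10)
  if (rank < n_components) {
    stop("data has spatial rank ", rank, " < n_components = ", n_components,
         call. = FALSE)
  }
  V <- eig$vectors[, seq_len(n_components), drop = FALSE]
  proj <- Mc %*% V
  data <- aperm(array(proj, c(d[1], d[3], n_components)), c(1, 3, 2))
  structure(list(data = data, times = epochs$times, sfreq = epochs$sfreq,
                 trial_table = epochs$trial_table,
                 rotation = V, center = mu, var_explained = eig$values,
                 source_channels = epochs$channel_names),
            class = "feature_epochs")
}

#' @export
print.feature_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat("<feature_epochs> ", d[1], " trials x ", d[2], " components x ",
      d[3], " samples\n", sep = "")
  invisible(x)
}

# near-equal partition sizes (differ by at most 1, larger bins first)
.bin_sizes <- function(n, b) {
  sizes <- rep(n %/% b, b)
  r <- n %% b
  if (r > 0) sizes[seq_len(r)] <- sizes[seq_len(r)] + 1
  sizes
}

#' Random sub-averaging of trials into bins (sub-ERPs)
#'
#' Randomly partitions rows into `n_bins` near-equal sets (sizes differing
#' by at most one) and averages within each set, raising the
#' signal-to-noise ratio of classifier exemplars.
#'
#' @param x numeric matrix, trials in rows.
#' @param n_bins number of sub-averages.
#' @param seed integer seed; the partition is deterministic given the seed.
#' @return List with `means` (`n_bins x ncol(x)`) and `assignment` (bin id
#'   per trial).
#' @export
bin_average <- function(x, n_bins, seed = 1) {
  n <- nrow(x)
  .assert(n >= n_bins, "fewer trials than bins")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, n, n_bins))
  ord <- sample(n)
  sizes <- .bin_sizes(n, n_bins)
  assignment <- integer(n)
  assignment[ord] <- rep(seq_len(n_bins), times = sizes)
  means <- do.call(rbind, lapply(seq_len(n_bins), function(b) {
    colMeans(x[assignment == b, , drop = FALSE])
  }))
  list(means = means, assignment = assignment)
}

#' Decoding specification
#'
#' Bundles the cross-validation design: `condition_pairwise` (binary
#' condition decoding; 10 sub-ERP bins, 10-fold CV) or `item_one_vs_all` /
#' `item_pairwise` (3 bins, 3-fold CV); classification runs at every
#' `step` ms with features averaged over +/- `smooth_halfwidth` ms
#' (half-open window) and is repeated for `n_iterations` random
#' train/test splits.
#'
#' @param mode decoding mode.
#' @param n_bins sub-ERP bins per class (= CV folds); defaults 10 for
#'   condition decoding, 3 for item decoding.
#' @param n_iterations random re-binning iterations (default 10).
#' @param step timepoint grid step, ms (default 20).
#' @param smooth_halfwidth half-width of the feature averaging window, ms
#'   (default 10).
#' @param subset_size item subset size for resampled item decoding
#'   (default 6).
#' @param seed master seed for all binning/subsetting randomness.
#' @return A `decode_spec` list; `n_folds` always equals `n_bins`.
#' @export
decode_spec <- function(mode = c("condition_pairwise", "item_one_vs_all",
                                 "item_pairwise"),
                        n_bins = NULL, n_iterations = 10, step = 20,
                        smooth_halfwidth = 10, subset_size = 6, seed = 1) {
  mode <- match.arg(mode)
  n_bins <- n_bins %||% if (mode == "condition_pairwise") 10L else 3L
  .assert(step > 0, "step must be positive")
  structure(list(mode = mode, n_bins = n_bins, n_folds = n_bins,
                 n_iterations = n_iterations, step = step,
                 smooth_halfwidth = smooth_halfwidth,
                 subset_size = subset_size, seed = seed),
            class = "decode_spec")
}

# linear-SVM multiclass prediction.
# condition mode: native libsvm one-vs-one voting.
# item mode: one binary SVM per class (class vs rest); assignment by
# maximum decision value, ties broken toward the lowest class index.
# Training rows are reordered so a target-class example comes first,
# pinning libsvm's +1 orientation to the target class.
.svm_predict <- function(trz, ytr, tez, k, mode) {
  if (mode == "condition_pairwise") {
    m <- e1071::svm(trz, factor(ytr, levels = seq_len(k)),
                    kernel = "linear", cost = 1, scale = FALSE)
    as.integer(as.character(stats::predict(m, tez)))
  } else {
    dv <- matrix(NA_real_, nrow(tez), k)
    for (c in seq_len(k)) {
      yy <- factor(ifelse(ytr == c, "target", "rest"),
                   levels = c("target", "rest"))
      ord <- order(yy != "target")
      m <- e1071::svm(trz[ord, , drop = FALSE], yy[ord],
                      kernel = "linear", cost = 1, scale = FALSE)
      p <- stats::predict(m, tez, decision.values = TRUE)
      dv[, c] <- attr(p, "decision.values")[, 1]
    }
    apply(dv, 1, which.max)
  }
}

# core engine: cross-validated decoding of a list of feature matrices
# (one per "point" - timepoint, frequency-timepoint, or searchlight
# window). Returns per-point accuracy plus the trial-level classification
# records that the permutation statistics reuse.
.decode_core <- function(Wlist, labels, spec, test_offset = 0) {
  labels <- droplevels(factor(labels))
  k <- nlevels(labels)
  .assert(k >= 2, "need at least 2 classes")
  counts <- table(labels)
  .assert(all(counts > 0), "class with zero trials")
  .assert(all(counts >= spec$n_bins), "fewer trials than bins for a class")
  n_bins <- spec$n_bins
  npts <- length(Wlist)
  n_ex <- k * n_bins
  n_it <- spec$n_iterations
  pred <- matrix(NA_integer_, n_it * n_ex, npts)
  true <- integer(n_it * n_ex)
  block <- rep(seq_len(n_it), each = n_ex)
  conf <- array(0, c(k, k, npts))
  lab_int <- as.integer(labels)

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  for (it in seq_len(n_it)) {
    set.seed(derive_seed(spec$seed, 7001, it))
    A <- matrix(0, n_ex, length(labels))
    row <- 0
    for (c in seq_len(k)) {
      idx <- sample(which(lab_int == c))
      sizes <- .bin_sizes(length(idx), n_bins)
      bnd <- cumsum(c(0, sizes))
      for (b in seq_len(n_bins)) {
        members <- idx[(bnd[b] + 1):bnd[b + 1]]
        A[row + b, members] <- 1 / length(members)
      }
      row <- row + n_bins
    }
    truth_it <- rep(seq_len(k), each = n_bins)
    B <- lapply(Wlist, function(W) A %*% W)
    base <- (it - 1) * n_ex
    true[base + seq_len(n_ex)] <- truth_it
    for (f in seq_len(n_bins)) {
      test_rows <- (seq_len(k) - 1) * n_bins + f
      train_rows <- setdiff(seq_len(n_ex), test_rows)
      ytr <- truth_it[train_rows]
      for (pt in seq_len(npts)) {
        tr <- B[[pt]][train_rows, , drop = FALSE]
        te <- B[[pt]][test_rows, , drop = FALSE] + test_offset
        mu <- colMeans(tr)
        s <- .col_sds(tr)
        s[s == 0 | is.na(s)] <- 1
        trz <- sweep(sweep(tr, 2, mu), 2, s, "/")
        tez <- sweep(sweep(te, 2, mu), 2, s, "/")
        p <- .svm_predict(trz, ytr, tez, k, spec$mode)
        pred[base + test_rows, pt] <- p
        for (i in seq_along(p)) {
          conf[truth_it[test_rows][i], p[i], pt] <-
            conf[truth_it[test_rows][i], p[i], pt] + 1
        }
      }
    }
  }
  list(accuracy = colMeans(pred == true), pred = pred, true = true,
       block = block, confusion = conf, k = k,
       classes = levels(labels))
}

# window-averaged feature matrices on the timepoint grid
.window_features <- function(x, spec, timepoints = NULL) {
  times <- x$times
  h <- spec$smooth_halfwidth
  grid <- timepoints %||% seq(times[1], times[length(times)], by = spec$step)
  keep <- logical(length(grid))
  Wlist <- vector("list", length(grid))
  for (g in seq_along(grid)) {
    idx <- time_window_idx(times, c(grid[g] - h, grid[g] + h))
    if (length(idx) == 0) next
    W <- rowMeans(x$data[, , idx, drop = FALSE], dims = 2)
    if (anyNA(W)) next
    Wlist[[g]] <- W
    keep[g] <- TRUE
  }
  list(grid = grid[keep], Wlist = Wlist[keep])
}

# default labels for a decoding mode
.decode_labels <- function(x, mode) {
  if (mode == "condition_pairwise") x$trial_table$condition else
    x$trial_table$item_id
}

#' Time-resolved cross-validated decoding
#'
#' The decoding engine: at every timepoint of a `step`-ms grid, features
#' are averaged over +/- `smooth_halfwidth` ms, trials of each class are
#' randomly sub-averaged into `n_bins` sub-ERPs, and a linear SVM is
#' trained/tested in an n-fold cross-validation (one sub-ERP per class
#' held out per fold), with train and test sets z-normalized by the
#' training mean and standard deviation only. The whole procedure repeats
#' for `n_iterations` random binnings and accuracies are averaged. For
#' item modes, class trial counts are first matched to the least-frequent
#' class.
#'
#' @param x a `feature_epochs` (or `epoch_set` for channel-space decoding).
#' @param spec a [decode_spec()].
#' @param labels per-trial class labels; defaults to the trial table's
#'   condition (condition mode) or item id (item modes).
#' @param timepoints explicit timepoint grid (ms); default every
#'   `spec$step` ms from the first sample.
#' @param test_offset constant added to test-fold features only; used by
#'   leakage probes and 0 in analysis.
#' @return A `decoding_result`: `accuracy` per timepoint, `times`, trial
#'   -level records (`pred`, `true`, `block`), `confusion`
#'   (classes x classes x timepoints) and `chance` (1 / n classes).
#' @export
decode_timecourse <- function(x, spec, labels = NULL, timepoints = NULL,
                              test_offset = 0) {
  labels <- labels %||% .decode_labels(x, spec$mode)
  labels <- droplevels(factor(labels))
  if (spec$mode != "condition_pairwise") {
    # match class counts to the smallest class
    counts <- table(labels)
    m <- min(counts)
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(derive_seed(spec$seed, 7002))
    keep <- sort(unlist(lapply(levels(labels), function(l) {
      idx <- which(labels == l)
      if (length(idx) > m) sample(idx, m) else idx
    })))
    x$data <- x$data[keep, , , drop = FALSE]
    x$trial_table <- x$trial_table[keep, , drop = FALSE]
    labels <- droplevels(labels[keep])
  }
  wf <- .window_features(x, spec, timepoints)
  .assert(length(wf$grid) > 0, "no decodable timepoints in the grid")
  core <- .decode_core(wf$Wlist, labels, spec, test_offset = test_offset)
  structure(list(accuracy = core$accuracy, times = wf$grid,
                 pred = core$pred, true = core$true, block = core$block,
                 confusion = core$confusion, classes = core$classes,
                 chance = 1 / core$k, spec = spec),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat("<decoding_result> ", length(x$classes), " classes, ",
      length(x$times), " timepoints; mean accuracy ",
      round(mean(x$accuracy), 4), " (chance ", round(x$chance, 4), ")\n",
      sep = "")
  invisible(x)
}

#' Empirical chance level from the pre-stimulus baseline
#'
#' Runs the full decoding procedure restricted to the pre-stimulus
#' baseline, where no task information exists, and returns the mean
#' accuracy: an empirical estimate of the chance level of the identical
#' analysis applied to post-stimulus data.
#'
#' @param x a `feature_epochs`.
#' @param spec a [decode_spec()].
#' @param labels per-trial labels (see [decode_timecourse()]).
#' @param baseline_window ms window, default `c(-500, 0)`.
#' @return Mean baseline accuracy (proportion).
#' @export
estimate_chance <- function(x, spec, labels = NULL,
                            baseline_window = c(-500, 0)) {
  grid <- seq(x$times[1], x$times[length(x$times)], by = spec$step)
  grid <- grid[grid >= baseline_window[1] & grid < baseline_window[2]]
  .assert(length(grid) > 0, "empty baseline window")
  res <- decode_timecourse(x, spec, labels = labels, timepoints = grid)
  mean(res$accuracy)
}

#' Resampled item decoding with a fixed subset size
#'
#' Makes 12-item conditions directly comparable with the 6-item Perceptual
#' Baseline: per iteration a random subset of `subset_size` items is drawn
#' and decoded one-vs-all (single binning per iteration); accuracies are
#' averaged over `n_iterations` subsets.
#'
#' @param x a `feature_epochs` restricted to one condition.
#' @param spec a [decode_spec()] (item mode).
#' @param subset_size items per subset (default 6).
#' @param n_iterations subset draws (default 20).
#' @param labels per-trial item labels (default from the trial table).
#' @param timepoints optional grid.
#' @return A `decoding_result` (accuracy averaged over subsets; records
#'   concatenated with one block per iteration; `chance = 1/subset_size`).
#' @export
decode_resampled_items <- function(x, spec, subset_size = 6,
                                   n_iterations = 20, labels = NULL,
                                   timepoints = NULL) {
  labels <- labels %||% x$trial_table$item_id
  labels <- droplevels(factor(labels))
  items <- levels(labels)
  .assert(subset_size <= length(items), "subset_size exceeds item count")
  acc <- NULL; preds <- list(); trues <- list(); blocks <- list()
  grid <- NULL
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  for (it in seq_len(n_iterations)) {
    set.seed(derive_seed(spec$seed, 7003, it))
    sub <- if (subset_size == length(items)) items else
      sample(items, subset_size)
    keep <- labels %in% sub
    xi <- x
    xi$data <- x$data[keep, , , drop = FALSE]
    xi$trial_table <- x$trial_table[keep, , drop = FALSE]
    sp <- spec; sp$n_iterations <- 1L; sp$seed <- derive_seed(spec$seed, it)
    r <- decode_timecourse(xi, sp, labels = droplevels(labels[keep]),
                           timepoints = timepoints)
    grid <- r$times
    acc <- if (is.null(acc)) r$accuracy else acc + r$accuracy
    preds[[it]] <- r$pred; trues[[it]] <- r$true
    blocks[[it]] <- rep(it, length(r$true))
  }
  structure(list(accuracy = acc / n_iterations, times = grid,
                 pred = do.call(rbind, preds), true = unlist(trues),
                 block = unlist(blocks), confusion = NULL,
                 classes = paste0("subset", seq_len(subset_size)),
                 chance = 1 / subset_size, spec = spec),
            class = "decoding_result")
}

#' Time-frequency-domain decoding
#'
#' Morlet-transforms PCA-reduced data (components treated as channels) and
#' applies the time-domain decoding procedure independently to the power
#' of each frequency bin, yielding a frequencies x timepoints accuracy
#' map. Edge samples without full wavelet support are excluded.
#'
#' @param x a `feature_epochs`.
#' @param spec a [decode_spec()].
#' @param labels per-trial labels.
#' @param freqs frequency grid (default [morlet_freqs()]).
#' @param timepoints optional timepoint grid.
#' @return A `tf_decoding_result`: `accuracy` (freqs x timepoints, `NA`
#'   where invalid), `freqs`, `times`, and per-record arrays `pred`
#'   (records x freqs x timepoints) and `true` for permutation inference.
#' @export
decode_timefrequency <- function(x, spec, labels = NULL,
                                 freqs = morlet_freqs(),
                                 timepoints = NULL) {
  labels <- labels %||% .decode_labels(x, spec$mode)
  tfr <- morlet_tfr(x, freqs)
  grid <- timepoints %||% seq(x$times[1], x$times[length(x$times)],
                              by = spec$step)
  acc <- matrix(NA_real_, length(freqs), length(grid))
  pred <- NULL; true <- NULL; block <- NULL
  for (fi in seq_along(freqs)) {
    xf <- list(data = tfr$power[, , fi, , drop = TRUE],
               times = tfr$times, sfreq = tfr$sfreq,
               trial_table = x$trial_table)
    dim(xf$data) <- dim(tfr$power)[c(1, 2, 4)]
    class(xf) <- "feature_epochs"
    r <- decode_timecourse(xf, spec, labels = labels, timepoints = grid)
    gi <- match(r$times, grid)
    acc[fi, gi] <- r$accuracy
    if (is.null(pred)) {
      pred <- array(NA_integer_, c(nrow(r$pred), length(freqs),
                                   length(grid)))
      true <- r$true; block <- r$block
    }
    pred[, fi, gi] <- r$pred
  }
  structure(list(accuracy = acc, freqs = freqs, times = grid,
                 pred = pred, true = true, block = block,
                 chance = 1 / length(unique(true)), spec = spec),
            class = "tf_decoding_result")
}

#' Average a time-frequency accuracy map over a band
#'
#' @param tfres a `tf_decoding_result`.
#' @param band Hz band, inclusive on bin centres (theta 4-8, alpha 9-12).
#' @return Accuracy timecourse (mean over the band's bins).
#' @export
tf_band_summary <- function(tfres, band) {
  fi <- which(tfres$freqs >= band[1] & tfres$freqs <= band[2])
  .assert(length(fi) > 0, "no bins in band")
  colMeans(tfres$accuracy[fi, , drop = FALSE], na.rm = TRUE)
}

#' Pairwise item decoding: neural RDM timecourse
#'
#' Binary decoding between every pair of items; the pairwise accuracy at
#' each timepoint is a dissimilarity estimate, assembled into a symmetric
#' item x item matrix per timepoint (the neural RDM series for RSA).
#'
#' @param x a `feature_epochs` restricted to one condition.
#' @param spec a [decode_spec()]; binning/folds follow the item design
#'   (3 bins, 3 folds by default).
#' @param labels per-trial item labels.
#' @param timepoints optional grid.
#' @return An `rdm_series`: array `items x items x timepoints` with `NA`
#'   diagonal, plus `times` and `items` attributes.
#' @export
pairwise_item_decode <- function(x, spec, labels = NULL, timepoints = NULL) {
  labels <- labels %||% x$trial_table$item_id
  labels <- droplevels(factor(labels))
  items <- levels(labels)
  .assert(length(items) >= 3, "need at least 3 items")
  pair_spec <- spec; pair_spec$mode <- "condition_pairwise"
  pair_spec$n_bins <- spec$n_bins; pair_spec$n_folds <- spec$n_bins
  grid <- NULL
  out <- NULL
  for (i in seq_along(items)[-length(items)]) {
    for (j in (i + 1):length(items)) {
      keep <- labels %in% items[c(i, j)]
      xi <- x
      xi$data <- x$data[keep, , , drop = FALSE]
      xi$trial_table <- x$trial_table[keep, , drop = FALSE]
      li <- droplevels(labels[keep])
      # equalize the pair's trial counts
      m <- min(table(li))
      sp <- pair_spec; sp$seed <- derive_seed(spec$seed, i, j)
      old <- .Random.seed_save()
      set.seed(derive_seed(spec$seed, 7004, i, j))
      keep2 <- sort(unlist(lapply(levels(li), function(l) {
        idx <- which(li == l)
        if (length(idx) > m) sample(idx, m) else idx
      })))
      .Random.seed_restore(old)
      xi$data <- xi$data[keep2, , , drop = FALSE]
      xi$trial_table <- xi$trial_table[keep2, , drop = FALSE]
      r <- decode_timecourse(xi, sp, labels = droplevels(li[keep2]),
                             timepoints = timepoints)
      if (is.null(out)) {
        grid <- r$times
        out <- array(NA_real_, c(length(items), length(items), length(grid)),
                     dimnames = list(items, items, NULL))
      }
      out[i, j, ] <- r$accuracy
      out[j, i, ] <- r$accuracy
    }
  }
  structure(out, times = grid, items = items, class = "rdm_series")
}
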