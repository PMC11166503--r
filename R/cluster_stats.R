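#' Group supra-threshold statistics into contiguous clusters
#'
#' Elements exceeding the cluster-forming threshold are grouped by
#' adjacency - consecutive samples on a 1-D time axis, 4-neighbour
#' contiguity on a 2-D time-frequency grid, or a channel neighbor graph -
#' and each cluster's mass is the sum of its member statistics.
#'
#' @param stat_values numeric vector (1-D), matrix (2-D grid), or vector
#'   over channels (graph adjacency).
#' @param threshold cluster-forming threshold (positive, finite).
#' @param adjacency `"time"`, `"grid"`, or a neighbor graph from
#'   [build_neighbors()].
#' @param tail `"pos"` clusters where `stat > threshold`, `"neg"` where
#'   `stat < -threshold`.
#' @return List of clusters, each `list(members, mass)`; members are
#'   indices into `stat_values` (linear indices for matrices).
#' @export
form_clusters <- function(stat_values, threshold, adjacency = "time",
                          tail = c("pos", "neg")) {
  tail <- match.arg(tail)
  .assert(is.finite(threshold), "threshold must be finite")
  v <- if (tail == "pos") stat_values else -stat_values
  supra <- v > threshold & !is.na(v)
  if (!any(supra)) return(list())
  if (identical(adjacency, "time")) {
    r <- rle(as.vector(supra))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    out <- list()
    for (k in which(r$values)) {
      members <- starts[k]:ends[k]
      out[[length(out) + 1]] <-
        list(members = members, mass = sum(stat_values[members]))
    }
    out
  } else if (identical(adjacency, "grid")) {
    .assert(is.matrix(stat_values), "grid adjacency needs a matrix")
    nr <- nrow(supra); nc <- ncol(supra)
    lab <- matrix(0L, nr, nc)
    nextlab <- 0L
    for (start in which(supra)) {
      if (lab[start] != 0L) next
      nextlab <- nextlab + 1L
      queue <- start
      lab[start] <- nextlab
      while (length(queue)) {
        cur <- queue[1]; queue <- queue[-1]
        i <- (cur - 1) %% nr + 1; j <- (cur - 1) %/% nr + 1
        for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
          ii <- i + d[1]; jj <- j + d[2]
          if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc) {
            lin <- (jj - 1) * nr + ii
            if (supra[lin] && lab[lin] == 0L) {
              lab[lin] <- nextlab
              queue <- c(queue, lin)
            }
          }
        }
      }
    }
    lapply(seq_len(nextlab), function(l) {
      members <- which(lab == l)
      list(members = members, mass = sum(stat_values[members]))
    })
  } else if (inherits(adjacency, "neighbor_graph")) {
    nb <- adjacency$neighbors
    visited <- rep(FALSE, length(supra))
    out <- list()
    for (s in which(supra)) {
      if (visited[s]) next
      comp <- integer(0)
      queue <- s; visited[s] <- TRUE
      while (length(queue)) {
        cur <- queue[1]; queue <- queue[-1]
        comp <- c(comp, cur)
        for (nbh in nb[[cur]]) {
          if (supra[nbh] && !visited[nbh]) {
            visited[nbh] <- TRUE
            queue <- c(queue, nbh)
          }
        }
      }
      out[[length(out) + 1]] <-
        list(members = sort(comp), mass = sum(stat_values[comp]))
    }
    out
  } else {
    stop("unknown adjacency", call. = FALSE)
  }
}

# max positive / min negative cluster mass of a statistic series
.max_mass <- function(stat, threshold, adjacency, tail) {
  cl <- form_clusters(stat, threshold, adjacency, tail)
  if (!length(cl)) return(0)
  max(vapply(cl, function(c) abs(c$mass), numeric(1)))
}

# assemble a cluster_test result object
.cluster_result <- function(stat, times, clusters_pos, clusters_neg,
                            null_pos, null_neg, threshold, n_perm,
                            cluster_alpha, tails, scheme) {
  mk <- function(cl, null, sign) {
    if (!length(cl)) return(NULL)
    do.call(rbind, lapply(cl, function(c) {
      mass <- abs(c$mass)
      p <- (sum(null >= mass) + 1) / (n_perm + 1)
      data.frame(start = min(c$members), end = max(c$members),
                 start_time = if (!is.null(times)) times[min(c$members)] else NA,
                 end_time = if (!is.null(times)) times[max(c$members)] else NA,
                 mass = c$mass, p = p, sign = sign,
                 significant = p <= cluster_alpha / tails)
    }))
  }
  clusters <- rbind(mk(clusters_pos, null_pos, "pos"),
                    mk(clusters_neg, null_neg, "neg"))
  structure(list(stat = stat, times = times, clusters = clusters,
                 null_pos = null_pos, null_neg = null_neg,
                 threshold = threshold, n_permutations = n_perm,
                 cluster_alpha = cluster_alpha, tails = tails,
                 scheme = scheme),
            class = "cluster_test")
}

#' @export
print.cluster_test <- function(x, ...) {
  cat("<cluster_test> scheme=", x$scheme, ", ", x$n_permutations,
      " permutations, threshold |t| > ", round(x$threshold, 3), "\n",
      sep = "")
  if (is.null(x$clusters)) cat("  no supra-threshold clusters\n")
  else print(x$clusters, row.names = FALSE)
  invisible(x)
}

#' Any significant cluster overlapping a time window?
#'
#' @param ct a `cluster_test`.
#' @param window ms window (half-open); `NULL` = anywhere.
#' @param sign `"pos"`, `"neg"` or `"any"`.
#' @return Logical.
#' @export
has_significant_cluster <- function(ct, window = NULL, sign = "any") {
  cl <- ct$clusters
  if (is.null(cl)) return(FALSE)
  cl <- cl[cl$significant, , drop = FALSE]
  if (sign != "any") cl <- cl[cl$sign == sign, , drop = FALSE]
  if (!is.null(window) && nrow(cl)) {
    cl <- cl[cl$end_time >= window[1] & cl$start_time < window[2], ,
             drop = FALSE]
  }
  nrow(cl) > 0
}

# restrict decoding results to the tested time range, returning list with
# accuracy matrix (participants x timepoints) and the time axis
.acc_matrix <- function(results, time_range) {
  times <- results[[1]]$times
  keep <- times >= time_range[1] & times <= time_range[2]
  acc <- do.call(rbind, lapply(results, function(r) r$accuracy[keep]))
  list(acc = acc, times = times[keep], keep = keep)
}

# B permutations of a label vector, shuffled within iteration blocks,
# as a B x n integer matrix
.perm_labels <- function(true, block, n_perm) {
  L <- matrix(0L, n_perm, length(true))
  blocks <- lapply(unique(block), function(b) which(block == b))
  for (b in seq_len(n_perm)) {
    tb <- true
    for (i in blocks) tb[i] <- sample(tb[i])
    L[b, ] <- tb
  }
  L
}

# paired/one-sample t maps for all permutations from accumulated
# per-participant permutation accuracies (sums and sums of squares)
.t_from_sums <- function(sumA, sumA2, P, mu) {
  m <- sumA / P
  v <- pmax(sumA2 - P * m^2, 0) / (P - 1)
  (m - mu) / sqrt(v / P)
}

#' Cluster permutation test of decoding accuracy against chance
#'
#' Observed statistic: one-tailed paired t of participant accuracies
#' against the chance level at every timepoint, clustered over contiguous
#' supra-threshold runs. Null: per permutation, each participant's
#' trial-level classification records are re-assigned to random classes
#' (true labels shuffled against fixed predictions), accuracies
#' recomputed, and the maximum cluster mass recorded; corrected p is the
#' fraction of null masses at least as large (with the `(b+1)/(m+1)`
#' convention).
#'
#' @param results list of `decoding_result` (one per participant, same
#'   timepoint grid).
#' @param chance chance level; default from the results.
#' @param n_perm permutations (default 1000).
#' @param cluster_alpha cluster-forming alpha (default 0.05, one-tailed).
#' @param time_range tested window in ms (default 0-3000).
#' @param seed permutation seed.
#' @return A `cluster_test`.
#' @export
perm_test_vs_chance <- function(results, chance = NULL, n_perm = 1000,
                                cluster_alpha = 0.05,
                                time_range = c(0, 3000), seed = 1) {
  .assert(all(vapply(results, function(r) !is.null(r$pred), logical(1))),
          "decoding results lack trial-level records")
  chance <- chance %||% results[[1]]$chance
  am <- .acc_matrix(results, time_range)
  P <- nrow(am$acc)
  thr <- stats::qt(1 - cluster_alpha, P - 1)
  tstat <- .col_t(am$acc, chance)
  obs <- form_clusters(tstat, thr, "time", "pos")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, 8001))
  Tn <- ncol(am$acc)
  sumA <- matrix(0, n_perm, Tn); sumA2 <- matrix(0, n_perm, Tn)
  for (p in seq_len(P)) {
    r <- results[[p]]
    pr <- r$pred[, am$keep, drop = FALSE]
    L <- .perm_labels(r$true, r$block, n_perm)
    accp <- matrix(0, n_perm, Tn)
    for (c in sort(unique(r$true))) {
      accp <- accp + (L == c) %*% (pr == c)
    }
    accp <- accp / nrow(pr)
    sumA <- sumA + accp; sumA2 <- sumA2 + accp^2
  }
  tmat <- .t_from_sums(sumA, sumA2, P, chance)
  null <- vapply(seq_len(n_perm), function(b)
    .max_mass(tmat[b, ], thr, "time", "pos"), numeric(1))
  .cluster_result(tstat, am$times, obs, list(), null, numeric(0),
                  thr, n_perm, cluster_alpha, 1, "vs-chance")
}

#' Cluster permutation test of a paired condition difference in decoding
#'
#' Observed: two-tailed paired t of per-participant accuracy differences
#' at each timepoint; positive and negative clusters formed separately.
#' Null: per permutation and participant, condition labels are randomly
#' re-assigned to the pooled trial-level classification records, both
#' accuracies recomputed, and the extreme cluster masses recorded for each
#' tail; critical values sit at the 2.5 % / 97.5 % points of the
#' respective tail's null.
#'
#' @param results_a,results_b paired lists of `decoding_result` (same
#'   participants, same grid).
#' @param n_perm permutations (default 1000).
#' @param cluster_alpha cluster-forming alpha (default 0.05, two-tailed).
#' @param time_range tested window (ms).
#' @param seed permutation seed.
#' @return A `cluster_test` with `pos` and `neg` clusters.
#' @export
perm_test_condition_diff <- function(results_a, results_b, n_perm = 1000,
                                     cluster_alpha = 0.05,
                                     time_range = c(0, 3000), seed = 1) {
  .assert(length(results_a) == length(results_b), "unpaired inputs")
  ama <- .acc_matrix(results_a, time_range)
  amb <- .acc_matrix(results_b, time_range)
  .assert(identical(ama$times, amb$times), "time grids differ")
  P <- nrow(ama$acc)
  thr <- stats::qt(1 - cluster_alpha / 2, P - 1)
  tstat <- .col_t(ama$acc - amb$acc, 0)
  obs_p <- form_clusters(tstat, thr, "time", "pos")
  obs_n <- form_clusters(tstat, thr, "time", "neg")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, 8002))
  Tn <- ncol(ama$acc)
  sumA <- matrix(0, n_perm, Tn); sumA2 <- matrix(0, n_perm, Tn)
  for (p in seq_len(P)) {
    ra <- results_a[[p]]; rb <- results_b[[p]]
    C <- rbind(ra$pred[, ama$keep, drop = FALSE] == ra$true,
               rb$pred[, amb$keep, drop = FALSE] == rb$true)
    na <- length(ra$true); n <- nrow(C)
    IND <- matrix(0, n_perm, n)
    for (b in seq_len(n_perm)) IND[b, sample(n, na)] <- 1
    diffp <- (IND %*% C) / na - ((1 - IND) %*% C) / (n - na)
    sumA <- sumA + diffp; sumA2 <- sumA2 + diffp^2
  }
  tmat <- .t_from_sums(sumA, sumA2, P, 0)
  null_p <- vapply(seq_len(n_perm), function(b)
    .max_mass(tmat[b, ], thr, "time", "pos"), numeric(1))
  null_n <- vapply(seq_len(n_perm), function(b)
    .max_mass(tmat[b, ], thr, "time", "neg"), numeric(1))
  .cluster_result(tstat, ama$times, obs_p, obs_n, null_p, null_n,
                  thr, n_perm, cluster_alpha, 2, "condition-diff")
}

#' Cluster permutation test of a between-group decoding difference
#'
#' Independent two-tailed t (pooled variance) at each timepoint between
#' two participant groups; the null shuffles group labels across
#' participants, preserving group sizes.
#'
#' @param results list of `decoding_result` per participant, or a
#'   participants x timepoints accuracy matrix (then supply `times`).
#' @param group_labels two-level factor over participants, >= 2 per group.
#' @param n_perm permutations.
#' @param cluster_alpha cluster-forming alpha (two-tailed).
#' @param time_range tested window (ms).
#' @param times time axis when `results` is a matrix.
#' @param seed permutation seed.
#' @return A `cluster_test`.
#' @export
perm_test_group_diff <- function(results, group_labels, n_perm = 1000,
                                 cluster_alpha = 0.05,
                                 time_range = c(0, 3000), times = NULL,
                                 seed = 1) {
  if (is.matrix(results)) {
    .assert(!is.null(times), "supply times with a matrix input")
    keep <- times >= time_range[1] & times <= time_range[2]
    acc <- results[, keep, drop = FALSE]
    tm <- times[keep]
  } else {
    am <- .acc_matrix(results, time_range)
    acc <- am$acc; tm <- am$times
  }
  g <- factor(group_labels)
  .assert(nlevels(g) == 2, "need exactly 2 groups")
  .assert(all(table(g) >= 2), "each group needs >= 2 members")
  i1 <- which(g == levels(g)[1]); i2 <- which(g == levels(g)[2])
  n1 <- length(i1); n2 <- length(i2)
  df <- n1 + n2 - 2
  thr <- stats::qt(1 - cluster_alpha / 2, df)
  tfun <- function(a1, a2) {
    m1 <- colMeans(a1); m2 <- colMeans(a2)
    v1 <- .col_sds(a1)^2; v2 <- .col_sds(a2)^2
    sp <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
    (m1 - m2) / sqrt(sp * (1 / n1 + 1 / n2))
  }
  tstat <- tfun(acc[i1, , drop = FALSE], acc[i2, , drop = FALSE])
  obs_p <- form_clusters(tstat, thr, "time", "pos")
  obs_n <- form_clusters(tstat, thr, "time", "neg")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, 8003))
  P <- nrow(acc)
  IND <- matrix(0, n_perm, P)
  for (b in seq_len(n_perm)) IND[b, sample(P, n1)] <- 1
  m1 <- (IND %*% acc) / n1
  m2 <- ((1 - IND) %*% acc) / n2
  q1 <- IND %*% acc^2
  q2 <- (1 - IND) %*% acc^2
  v1 <- pmax(q1 - n1 * m1^2, 0) / (n1 - 1)
  v2 <- pmax(q2 - n2 * m2^2, 0) / (n2 - 1)
  sp <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
  tmat <- (m1 - m2) / sqrt(sp * (1 / n1 + 1 / n2))
  null_p <- vapply(seq_len(n_perm), function(b)
    .max_mass(tmat[b, ], thr, "time", "pos"), numeric(1))
  null_n <- vapply(seq_len(n_perm), function(b)
    .max_mass(tmat[b, ], thr, "time", "neg"), numeric(1))
  .cluster_result(tstat, tm, obs_p, obs_n, null_p, null_n,
                  thr, n_perm, cluster_alpha, 2, "group-diff")
}

#' Spearman rho to t transform
#'
#' `t = rho * sqrt((n - 2) / (1 - rho^2))`; `|rho| = 1` is capped just
#' below 1 with a warning (infinite t otherwise).
#'
#' @param rho correlation(s).
#' @param n sample size.
#' @return t value(s).
#' @export
rho_to_t <- function(rho, n) {
  if (any(abs(rho) >= 1, na.rm = TRUE)) {
    warning("|rho| = 1 capped for the t transform")
    rho <- pmin(pmax(rho, -1 + 1e-12), 1 - 1e-12)
  }
  rho * sqrt((n - 2) / (1 - rho^2))
}

#' Cluster permutation test of a correlation timecourse
#'
#' Spearman correlation between a per-participant timecourse (e.g.
#' decoding accuracy) and a per-participant scalar (e.g. memory score) at
#' every timepoint; rho is transformed to t, clustered on both tails, and
#' compared against a null built by shuffling the pairing between the two
#' variables across participants.
#'
#' @param x participants x timepoints matrix.
#' @param y participant scalar vector.
#' @param n_perm permutations.
#' @param cluster_alpha cluster-forming alpha (two-tailed).
#' @param times optional time axis.
#' @param seed permutation seed.
#' @return A `cluster_test`.
#' @export
corr_cluster_timecourse <- function(x, y, n_perm = 1000,
                                    cluster_alpha = 0.05, times = NULL,
                                    seed = 1) {
  n <- nrow(x)
  .assert(n >= 4, "need >= 4 participants")
  .assert(length(y) == n, "x, y dimension mismatch")
  rx <- apply(x, 2, rank)
  rxs <- scale(rx)                      # rank columns, standardized
  rho_series <- function(yy) {
    ry <- as.vector(scale(rank(yy)))
    as.vector(crossprod(ry, rxs)) / (n - 1)
  }
  thr <- stats::qt(1 - cluster_alpha / 2, n - 2)
  tstat <- rho_to_t(rho_series(y), n)
  obs_p <- form_clusters(tstat, thr, "time", "pos")
  obs_n <- form_clusters(tstat, thr, "time", "neg")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, 8004))
  ry <- as.vector(scale(rank(y)))
  RY <- matrix(0, n_perm, n)
  for (b in seq_len(n_perm)) RY[b, ] <- ry[sample(n)]
  rmat <- (RY %*% rxs) / (n - 1)
  tmat <- suppressWarnings(rho_to_t(rmat, n))
  null_p <- vapply(seq_len(n_perm), function(b)
    .max_mass(tmat[b, ], thr, "time", "pos"), numeric(1))
  null_n <- vapply(seq_len(n_perm), function(b)
    .max_mass(tmat[b, ], thr, "time", "neg"), numeric(1))
  .cluster_result(tstat, times, obs_p, obs_n, null_p, null_n,
                  thr, n_perm, cluster_alpha, 2, "correlation")
}

#' 2-D cluster permutation test of time-frequency decoding vs chance
#'
#' Like [perm_test_vs_chance()] but on frequencies x timepoints accuracy
#' maps with 4-neighbour grid clustering, and with rank matching: the
#' k-th largest observed cluster is compared against the null distribution
#' of k-th largest cluster masses.
#'
#' @param results list of `tf_decoding_result` per participant.
#' @param chance chance level.
#' @param n_perm permutations.
#' @param cluster_alpha cluster-forming alpha (one-tailed vs chance).
#' @param time_range tested window (ms).
#' @param seed permutation seed.
#' @return A `cluster_test`; cluster rows carry `rank`.
#' @export
perm_test_tf_vs_chance <- function(results, chance = NULL, n_perm = 1000,
                                   cluster_alpha = 0.05,
                                   time_range = c(0, 3000), seed = 1) {
  chance <- chance %||% results[[1]]$chance
  times <- results[[1]]$times
  keep <- times >= time_range[1] & times <= time_range[2]
  P <- length(results)
  F <- length(results[[1]]$freqs)
  Tn <- sum(keep)
  thr <- stats::qt(1 - cluster_alpha, P - 1)
  amaps <- lapply(results, function(r) r$accuracy[, keep, drop = FALSE])
  tmap <- matrix(NA_real_, F, Tn)
  for (fi in seq_len(F)) {
    m <- do.call(rbind, lapply(amaps, function(a) a[fi, ]))
    tmap[fi, ] <- .col_t(m, chance)
  }
  obs <- form_clusters(tmap, thr, "grid", "pos")
  ord <- order(vapply(obs, function(c) -abs(c$mass), numeric(1)))
  obs <- obs[ord]
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, 8005))
  kmax <- max(1L, length(obs))
  nullm <- matrix(0, n_perm, kmax)
  for (b in seq_len(n_perm)) {
    tb <- matrix(NA_real_, F, Tn)
    accb <- vector("list", P)
    for (p in seq_len(P)) {
      r <- results[[p]]
      tbl <- r$true
      for (blk in unique(r$block)) {
        i <- which(r$block == blk)
        tbl[i] <- sample(tbl[i])
      }
      eq <- r$pred[, , keep, drop = FALSE] == tbl
      accb[[p]] <- apply(eq, c(2, 3), mean)
    }
    for (fi in seq_len(F)) {
      m <- do.call(rbind, lapply(accb, function(a) a[fi, ]))
      tb[fi, ] <- .col_t(m, chance)
    }
    cl <- form_clusters(tb, thr, "grid", "pos")
    masses <- sort(vapply(cl, function(c) abs(c$mass), numeric(1)),
                   decreasing = TRUE)
    nullm[b, seq_len(min(kmax, length(masses)))] <-
      masses[seq_len(min(kmax, length(masses)))]
  }
  clusters <- NULL
  if (length(obs)) {
    clusters <- do.call(rbind, lapply(seq_along(obs), function(k) {
      mass <- abs(obs[[k]]$mass)
      nd <- nullm[, min(k, kmax)]
      data.frame(rank = k, size = length(obs[[k]]$members),
                 mass = obs[[k]]$mass,
                 p = (sum(nd >= mass) + 1) / (n_perm + 1),
                 sign = "pos",
                 significant = (sum(nd >= mass) + 1) / (n_perm + 1) <=
                   cluster_alpha)
    }))
  }
  structure(list(stat = tmap, times = times[keep],
                 freqs = results[[1]]$freqs, clusters = clusters,
                 null_ranked = nullm, threshold = thr,
                 n_permutations = n_perm, cluster_alpha = cluster_alpha,
                 tails = 1, scheme = "tf-vs-chance"),
            class = "cluster_test")
}
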