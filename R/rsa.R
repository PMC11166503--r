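#' Average per-rater subjective ratings into a group RDM
#'
#' Element-wise mean over raters, converted so larger = more dissimilar.
#' Raters score on a 1 (extremely dissimilar) - 9 (extremely similar)
#' scale, so with `direction = "similarity"` (the default reading of that
#' anchor text) the averaged rating r becomes dissimilarity `10 - r`; set
#' `direction = "dissimilarity"` if the ratings are already
#' dissimilarities. The result is symmetrized by averaging with its
#' transpose; the diagonal is `NA` and excluded from all statistics.
#'
#' @param stack `raters x items x items` array (item dimnames).
#' @param direction scale orientation of the raw ratings.
#' @return An `rdm`: symmetric items x items matrix, `NA` diagonal.
#' @export
average_subjective_rdm <- function(stack,
                                   direction = c("similarity",
                                                 "dissimilarity")) {
  direction <- match.arg(direction)
  .assert(length(dim(stack)) == 3 && dim(stack)[2] == dim(stack)[3],
          "stack must be raters x items x items")
  m <- apply(stack, c(2, 3), mean, na.rm = TRUE)
  if (direction == "similarity") m <- 10 - m
  m <- (m + t(m)) / 2
  diag(m) <- NA_real_
  structure(m, class = c("rdm", "matrix"))
}

# lower-triangle vectorization, fixed row-major order (i < j), shared by
# every RDM comparison so orderings always match
.rdm_vec <- function(m) {
  m <- unclass(m)
  t(m)[lower.tri(m)]
}

#' Average a neural RDM series over a time window
#'
#' Pairwise decoding accuracy at a single timepoint rides on the
#' oscillatory carrier of the underlying patterns; averaging the RDM over
#' a window of timepoints gives a stable estimate of the item geometry in
#' that window (used for window-level RSA summaries).
#'
#' @param series an `rdm_series` from [pairwise_item_decode()].
#' @param window ms window (half-open); `NULL` = all timepoints.
#' @return An `rdm` (items x items, `NA` diagonal).
#' @export
average_rdm_series <- function(series, window = NULL) {
  times <- attr(series, "times")
  keep <- if (is.null(window)) rep(TRUE, length(times)) else
    times >= window[1] & times < window[2]
  .assert(any(keep), "window selects no timepoints")
  m <- apply(unclass(series)[, , keep, drop = FALSE], c(1, 2), mean)
  diag(m) <- NA_real_
  structure(m, class = c("rdm", "matrix"))
}

#' Spearman correlation between two RDMs' lower triangles
#'
#' @param a,b `rdm` objects over the same items.
#' @param tails 1 (positive) or 2.
#' @return A `stat_result` with rho and p (t approximation over pairs).
#' @export
rdm_correlation <- function(a, b, tails = 1) {
  .assert(identical(sort(rownames(a)), sort(rownames(b))),
          "item sets differ between RDMs")
  b <- b[rownames(a), rownames(a)]
  va <- .rdm_vec(a); vb <- .rdm_vec(b)
  rho <- stats::cor(rank(va), rank(vb))
  tt <- suppressWarnings(rho_to_t(rho, length(va)))
  p <- if (tails == 1) stats::pt(tt, length(va) - 2, lower.tail = FALSE)
       else 2 * stats::pt(-abs(tt), length(va) - 2)
  structure(list(statistic = "rho", value = rho, df = length(va) - 2,
                 p = p, effect_size = rho, effect_size_name = "rho",
                 tails = tails),
            class = "stat_result")
}

#' RSA timecourse: neural RDM series vs a subjective RDM
#'
#' Spearman correlation between the lower triangles of the neural RDM at
#' every timepoint and a fixed subjective RDM, with one-sided p (positive
#' tail, t approximation over the n(n-1)/2 item pairs) reported inside the
#' mask of significant item-decoding timepoints and `NA` outside
#' (uncorrected, a-priori masked test). Pre-stimulus timepoints are
#' flagged so unexpectedly high baseline correlations are visible rather
#' than silently pooled.
#'
#' @param neural an `rdm_series` from [pairwise_item_decode()].
#' @param subjective an `rdm` with the same items.
#' @param mask logical vector over timepoints, or a list of ms windows, or
#'   `NULL` (all timepoints tested).
#' @return data.frame `time, rho, p, in_mask, prestim`.
#' @export
rsa_timecourse <- function(neural, subjective, mask = NULL) {
  items <- attr(neural, "items")
  .assert(identical(sort(items), sort(rownames(subjective))),
          "item sets differ between neural and subjective RDMs")
  subjective <- subjective[items, items]
  times <- attr(neural, "times")
  sv <- .rdm_vec(subjective)
  npair <- length(sv)
  if (is.list(mask)) {
    m <- rep(FALSE, length(times))
    for (w in mask) m <- m | (times >= w[1] & times < w[2])
    mask <- m
  }
  mask <- mask %||% rep(TRUE, length(times))
  rho <- numeric(length(times)); p <- rep(NA_real_, length(times))
  for (ti in seq_along(times)) {
    nv <- .rdm_vec(unclass(neural)[, , ti])
    if (stats::sd(nv) == 0 || stats::sd(sv) == 0) {
      warning("constant RDM triangle at timepoint ", times[ti])
      rho[ti] <- NA_real_
      next
    }
    rho[ti] <- stats::cor(rank(nv), rank(sv))
    if (mask[ti]) {
      tt <- suppressWarnings(rho_to_t(rho[ti], npair))
      p[ti] <- stats::pt(tt, npair - 2, lower.tail = FALSE)
    }
  }
  data.frame(time = times, rho = rho, p = p, in_mask = mask,
             prestim = times < 0)
}
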