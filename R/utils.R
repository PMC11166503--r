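#' Derive a reproducible child seed from a master seed
#'
#' Every stochastic stage of the pipeline draws its own seed from a master
#' seed plus a stream identifier, so that stages are independently
#' reproducible and adding a stage never shifts the random stream of another.
#'
#' @param seed master seed (integer-valued).
#' @param ... further integer stream identifiers (participant index,
#'   iteration number, ...).
#' @return An integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  ids <- c(seed, ...)
  x <- 0
  m <- 2147483629  # prime below 2^31
  for (k in ids) {
    x <- (x * 69069 + (as.numeric(k) %% m) + 1) %% m
  }
  as.integer(x + 1)
}

#' Indices of samples falling in a half-open time window
#'
#' All time windows in the package are half-open `[start, end)` in
#' milliseconds relative to cue onset.
#'
#' @param times numeric vector of sample times (ms).
#' @param window length-2 numeric, `c(start, end)` in ms.
#' @return Integer indices into `times`.
#' @export
time_window_idx <- function(times, window) {
  stopifnot(length(window) == 2, window[1] < window[2])
  which(times >= window[1] & times < window[2])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# column means / sds without matrixStats
.col_sds <- function(x) {
  n <- nrow(x)
  if (n < 2) return(rep(NA_real_, ncol(x)))
  m <- colMeans(x)
  sqrt(pmax(colSums(x^2) - n * m^2, 0) / (n - 1))
}

# per-column paired/one-sample t statistic of matrix rows vs mu
.col_t <- function(x, mu = 0) {
  n <- nrow(x)
  m <- colMeans(x)
  s <- .col_sds(x)
  s[s == 0 | is.na(s)] <- NA_real_
  (m - mu) / (s / sqrt(n))
}

.assert <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)
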