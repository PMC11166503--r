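#' One-way repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Classic within-subject F test over k conditions with partial eta
#' squared; the Greenhouse-Geisser epsilon is estimated from the sample
#' covariance of the condition scores and applied to the degrees of
#' freedom whenever sphericity cannot be assumed (epsilon is bounded below
#' by `1/(k-1)` and above by 1).
#'
#' @param scores participants x conditions matrix (no missing cells,
#'   n >= 3).
#' @return A `stat_result` with `F`, uncorrected and GG-corrected df and
#'   p, `epsilon`, and partial eta squared.
#' @export
rm_anova_gg <- function(scores) {
  scores <- as.matrix(scores)
  n <- nrow(scores); k <- ncol(scores)
  .assert(n >= 3, "need >= 3 participants")
  .assert(!anyNA(scores), "missing cells")
  grand <- mean(scores)
  subj_m <- rowMeans(scores); cond_m <- colMeans(scores)
  ss_cond <- n * sum((cond_m - grand)^2)
  ss_err <- sum((scores - outer(subj_m, cond_m, "+") + grand)^2)
  .assert(ss_err > 0, "zero error variance (constant data)")
  df1 <- k - 1; df2 <- (k - 1) * (n - 1)
  Fv <- (ss_cond / df1) / (ss_err / df2)
  S <- stats::cov(scores)
  Cc <- diag(k) - matrix(1 / k, k, k)
  Sc <- Cc %*% S %*% Cc
  eps <- sum(diag(Sc))^2 / (df1 * sum(Sc^2))
  eps <- min(max(eps, 1 / df1), 1)
  p_unc <- stats::pf(Fv, df1, df2, lower.tail = FALSE)
  p_gg <- stats::pf(Fv, eps * df1, eps * df2, lower.tail = FALSE)
  structure(list(statistic = "F", value = Fv,
                 df = c(df1, df2), df_gg = c(eps * df1, eps * df2),
                 epsilon = eps, p_uncorrected = p_unc, p = p_gg,
                 effect_size = ss_cond / (ss_cond + ss_err),
                 effect_size_name = "partial_eta_sq", tails = NA),
            class = "stat_result")
}

#' Paired t-test with Cohen's dz
#'
#' `dz = mean(a - b) / sd(a - b)`; for paired designs `dz = t / sqrt(n)`.
#'
#' @param a,b paired score vectors.
#' @param tails 1 or 2 (default 2).
#' @return A `stat_result` with `t`, df, p, dz.
#' @export
paired_t_dz <- function(a, b, tails = 2) {
  .assert(length(a) == length(b), "unequal lengths")
  n <- length(a)
  .assert(n >= 2, "need n >= 2")
  d <- a - b
  .assert(stats::sd(d) > 0, "zero-variance differences (dz undefined)")
  tv <- mean(d) / (stats::sd(d) / sqrt(n))
  p <- if (tails == 2) 2 * stats::pt(-abs(tv), n - 1) else
    stats::pt(abs(tv), n - 1, lower.tail = FALSE)
  structure(list(statistic = "t", value = tv, df = n - 1, p = p,
                 effect_size = mean(d) / stats::sd(d),
                 effect_size_name = "dz", tails = tails),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat("<stat_result> ", x$statistic, "(",
      paste(round(x$df, 2), collapse = ", "), ") = ", round(x$value, 3),
      ", p = ", signif(x$p, 3), ", ", x$effect_size_name, " = ",
      round(x$effect_size, 3), "\n", sep = "")
  invisible(x)
}

#' Split participants into low/high suppression groups
#'
#' `median`: rank by score (ties and odd n broken deterministically by
#' participant order), first half = `"low"`. `kmeans2`: exact 1-D 2-means
#' (every split point of the sorted scores scanned, minimal within-group
#' sum of squares; deterministic), groups labelled by mean score.
#'
#' @param scores numeric forgetting scores (e.g. Baseline minus No-Think
#'   Detail), n >= 4, not all identical.
#' @param method `"median"` or `"kmeans2"`.
#' @return Factor of `"low"` / `"high"` per participant.
#' @export
split_groups <- function(scores, method = c("median", "kmeans2")) {
  method <- match.arg(method)
  n <- length(scores)
  .assert(n >= 4, "need >= 4 participants")
  .assert(stats::sd(scores) > 0, "all scores identical")
  if (method == "median") {
    ord <- order(scores, seq_len(n))
    g <- character(n)
    g[ord] <- rep(c("low", "high"), c(ceiling(n / 2), floor(n / 2)))
    factor(g, levels = c("low", "high"))
  } else {
    ord <- order(scores)
    s <- scores[ord]
    best <- NULL; best_ss <- Inf
    for (cut in seq_len(n - 1)) {
      ss <- sum((s[1:cut] - mean(s[1:cut]))^2) +
        sum((s[(cut + 1):n] - mean(s[(cut + 1):n]))^2)
      if (ss < best_ss - 1e-12) { best_ss <- ss; best <- cut }
    }
    g <- character(n)
    g[ord] <- rep(c("low", "high"), c(best, n - best))
    factor(g, levels = c("low", "high"))
  }
}

#' Spearman brain-behavior correlation
#'
#' Optionally normalizes the behavioral score relative to Baseline as
#' `(x - baseline) / baseline` before correlating (zero Baseline gives a
#' flagged missing value).
#'
#' @param brain per-participant decoding metric.
#' @param behavior per-participant memory score.
#' @param baseline optional per-participant Baseline score for
#'   normalization.
#' @param tails 1 or 2.
#' @return A `stat_result` with rho and p.
#' @export
spearman_brainbehavior <- function(brain, behavior, baseline = NULL,
                                   tails = 2) {
  .assert(length(brain) == length(behavior), "length mismatch")
  .assert(length(brain) >= 4, "need >= 4 participants")
  if (!is.null(baseline)) {
    bad <- baseline == 0
    if (any(bad)) {
      warning("Baseline = 0 for ", sum(bad),
              " participant(s); normalized score set NA")
      behavior[bad] <- NA
    }
    behavior <- (behavior - baseline) / baseline
  }
  ok <- stats::complete.cases(brain, behavior)
  .assert(stats::sd(brain[ok]) > 0 && stats::sd(behavior[ok]) > 0,
          "zero-variance input")
  ct <- suppressWarnings(
    stats::cor.test(brain[ok], behavior[ok], method = "spearman",
                    alternative = if (tails == 2) "two.sided" else "greater",
                    exact = FALSE))
  structure(list(statistic = "rho", value = unname(ct$estimate),
                 df = sum(ok) - 2, p = ct$p.value,
                 effect_size = unname(ct$estimate),
                 effect_size_name = "rho", tails = tails),
            class = "stat_result")
}

#' Compare two dependent correlations sharing a variable
#'
#' Two-sided z test for the difference between correlations r1 = r(x, y1)
#' and r2 = r(x, y2) measured on the same sample, controlling for the
#' dependence through r(y1, y2) (the Meng-Rosenthal-Rubin procedure on
#' Fisher-transformed correlations).
#'
#' @param r1,r2 the two correlations with the shared variable.
#' @param r_between correlation between the two non-shared variables.
#' @param n sample size (>= 4).
#' @return A `stat_result` with z and two-sided p.
#' @export
compare_dependent_correlations <- function(r1, r2, r_between, n) {
  .assert(all(abs(c(r1, r2, r_between)) < 1), "correlations must be in (-1, 1)")
  .assert(n >= 4, "need n >= 4")
  rm2 <- (r1^2 + r2^2) / 2
  f <- min((1 - r_between) / (2 * (1 - rm2)), 1)
  h <- (1 - f * rm2) / (1 - rm2)
  z1 <- atanh(r1); z2 <- atanh(r2)
  z <- (z1 - z2) * sqrt((n - 3) / (2 * (1 - r_between) * h))
  structure(list(statistic = "z", value = z, df = NA,
                 p = 2 * stats::pnorm(-abs(z)),
                 effect_size = r1 - r2, effect_size_name = "r1 - r2",
                 tails = 2),
            class = "stat_result")
}

#' Exact power of a paired / one-sample t-test
#'
#' Noncentral-t power for effect size dz at sample size n:
#' `power = P(|T'| > t_crit)` with noncentrality `dz * sqrt(n)`.
#'
#' @param n sample size (>= 2).
#' @param dz effect size (Cohen's dz).
#' @param alpha false-positive rate in (0, 1).
#' @param tails 1 or 2 (default 2).
#' @return Power (proportion).
#' @export
power_paired_t <- function(n, dz, alpha = 0.05, tails = 2) {
  .assert(n >= 2, "need n >= 2")
  .assert(alpha > 0 && alpha < 1, "alpha must be in (0, 1)")
  df <- n - 1
  ncp <- dz * sqrt(n)
  crit <- stats::qt(1 - alpha / tails, df)
  pow <- stats::pt(crit, df, ncp = ncp, lower.tail = FALSE)
  if (tails == 2) pow <- pow + stats::pt(-crit, df, ncp = ncp)
  pow
}
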