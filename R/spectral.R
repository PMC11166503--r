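#' Frequency grid for time-frequency analysis
#'
#' 22 geometrically spaced frequencies from 2.8 to 30 Hz (both endpoints
#' included), the grid used throughout the oscillation analyses.
#'
#' @param n number of bins.
#' @param fmin,fmax grid endpoints in Hz.
#' @return Numeric vector of frequencies.
#' @export
morlet_freqs <- function(n = 22, fmin = 2.8, fmax = 30) {
  exp(seq(log(fmin), log(fmax), length.out = n))
}

#' Wavelet cycle counts: linear from 3 at 2.8 Hz to 7 at 30 Hz
#'
#' @param freqs frequencies in Hz.
#' @param fmin,fmax frequency range over which cycles ramp from `cmin` to
#'   `cmax`.
#' @param cmin,cmax cycle counts at `fmin` and `fmax`.
#' @return Numeric vector of cycle counts.
#' @export
morlet_cycles <- function(freqs, fmin = 2.8, fmax = 30, cmin = 3, cmax = 7) {
  cmin + (cmax - cmin) * (freqs - fmin) / (fmax - fmin)
}

#' Morlet wavelet time-frequency decomposition
#'
#' Convolves every trial and channel with complex Morlet wavelets
#' (Gaussian sd in time `= cycles / (2 pi f)`, support truncated at
#' +/- 3 sd) and returns single-trial power. Samples whose wavelet extends
#' beyond the epoch are marked invalid (`NA`) rather than silently
#' zero-padded; at 2.8 Hz with 3 cycles that invalidates roughly the first
#' and last half second of an epoch.
#'
#' @param x an `epoch_set` or `feature_epochs` (components are treated as
#'   channels).
#' @param freqs frequency grid, default [morlet_freqs()].
#' @param cycles cycle counts, default [morlet_cycles()] on `freqs`.
#' @param decim keep every `decim`-th output sample (power varies slowly,
#'   so decimating the output keeps single-trial TFRs of long epochs at a
#'   workable size; 1 = no decimation).
#' @return A `tfr_set`: `power` array `trials x channels x freqs x times`
#'   (uV^2, `NA` where invalid), `freqs`, `times`, `sfreq`, `trial_table`,
#'   `baseline_state = "raw"`.
#' @export
morlet_tfr <- function(x, freqs = morlet_freqs(),
                       cycles = morlet_cycles(freqs), decim = 1) {
  .assert(all(diff(freqs) > 0), "freqs must be strictly increasing")
  arr <- x$data
  nt <- dim(arr)[3]; nch <- dim(arr)[2]; ntr <- dim(arr)[1]
  sfreq <- x$sfreq
  dt <- 1 / sfreq
  sd_t <- cycles / (2 * pi * freqs)
  half <- ceiling(3 * sd_t / dt)
  .assert(any(half < (nt - 1) / 2),
          "epoch too short for the lowest frequency wavelet")
  nfft <- stats::nextn(nt + 2 * max(half), 2)
  tidx <- seq(1, nt, by = decim)

  # precompute wavelet spectra
  FWs <- lapply(seq_along(freqs), function(fi) {
    h <- half[fi]
    tv <- (-h:h) * dt
    w <- exp(2i * pi * freqs[fi] * tv) * exp(-tv^2 / (2 * sd_t[fi]^2))
    w <- w / sqrt(sum(Mod(w)^2))
    stats::fft(c(w, rep(0, nfft - length(w))))
  })

  power <- array(NA_real_, c(ntr, nch, length(freqs), length(tidx)))
  # chunk the trial x channel columns so complex intermediates stay small
  cols <- ntr * nch
  M <- matrix(aperm(arr, c(3, 1, 2)), nrow = nt)
  chunk <- max(1L, floor(4e6 / nfft))
  starts <- seq(1, cols, by = chunk)
  for (s in starts) {
    jj <- s:min(s + chunk - 1, cols)
    Mp <- rbind(M[, jj, drop = FALSE],
                matrix(0, nfft - nt, length(jj)))
    FM <- stats::mvfft(Mp)
    for (fi in seq_along(freqs)) {
      h <- half[fi]
      conv <- stats::mvfft(FM * FWs[[fi]], inverse = TRUE) / nfft
      seg <- conv[h + tidx, , drop = FALSE]   # centre-aligned
      p <- Mod(seg)^2
      valid <- tidx > h & tidx <= nt - h
      p[!valid, ] <- NA_real_
      # columns jj map back to (trial, channel) pairs
      tr_i <- (jj - 1) %% ntr + 1
      ch_i <- (jj - 1) %/% ntr + 1
      for (q in seq_along(jj)) {
        power[tr_i[q], ch_i[q], fi, ] <- p[, q]
      }
    }
  }
  structure(list(power = power, freqs = freqs, cycles = cycles,
                 times = x$times[tidx], sfreq = sfreq / decim,
                 channel_names = x$channel_names %||%
                   paste0("C", seq_len(nch)),
                 trial_table = x$trial_table,
                 baseline_state = "raw"),
            class = "tfr_set")
}

#' @export
print.tfr_set <- function(x, ...) {
  d <- dim(x$power)
  cat("<tfr_set> ", d[1], " trials x ", d[2], " channels x ", d[3],
      " freqs x ", d[4], " samples (", x$baseline_state, ")\n", sep = "")
  invisible(x)
}

#' Decibel baseline normalization of a TFR
#'
#' Converts power to `10 log10(power / baseline)`, where the baseline is
#' the mean raw power per channel and frequency over the baseline window,
#' pooled over trials and conditions (the stable, standard dB convention).
#' Invalid (edge) samples inside the window are ignored.
#'
#' @param tfr a raw `tfr_set`.
#' @param window baseline window in ms, default `c(-500, -200)`.
#' @return The `tfr_set` in dB (`baseline_state = "dB"`).
#' @export
db_baseline <- function(tfr, window = c(-500, -200)) {
  .assert(inherits(tfr, "tfr_set"), "not a tfr_set")
  .assert(tfr$baseline_state == "raw", "tfr already baselined")
  idx <- time_window_idx(tfr$times, window)
  .assert(length(idx) > 0, "baseline window outside the epoch")
  base <- apply(tfr$power[, , , idx, drop = FALSE], c(2, 3), mean,
                na.rm = TRUE)
  .assert(all(is.finite(base)),
          "no valid baseline samples for some channel x frequency")
  .assert(all(base > 0), "nonpositive baseline power")
  d <- dim(tfr$power)
  bl <- aperm(array(base, c(d[2], d[3], d[1], d[4])), c(3, 1, 2, 4))
  tfr$power <- 10 * log10(tfr$power / bl)
  tfr$baseline_state <- "dB"
  tfr
}

#' Average TFR power over a frequency band and time window
#'
#' @param tfr a `tfr_set` (raw or dB).
#' @param band frequency band in Hz, inclusive `[lo, hi]` on bin centres
#'   (theta = 4-8, alpha = 9-12).
#' @param window time window in ms, half-open.
#' @return `trials x channels` matrix of band power.
#' @export
band_power <- function(tfr, band, window) {
  fi <- which(tfr$freqs >= band[1] & tfr$freqs <= band[2])
  ti <- time_window_idx(tfr$times, window)
  .assert(length(fi) > 0, "no frequency bins in band")
  .assert(length(ti) > 0, "no samples in window")
  apply(tfr$power[, , fi, ti, drop = FALSE], c(1, 2), mean, na.rm = TRUE)
}

#' ERP component definitions
#'
#' Named electrode clusters and time windows for the components the
#' univariate analyses target: the frontocentral N450 (300-500 ms), the
#' parietal P300 (300-800 ms), and the left prefrontal negative slow wave
#' (500-3000 ms; slow-wave window fixed by this package since component
#' conventions give no sharp bound).
#'
#' @param name `"N450"`, `"P300"` or `"NSW"`.
#' @param electrodes,window override the preset cluster / window.
#' @return An `erp_component_spec` list with `name`, `electrodes`, `window`.
#' @export
erp_component_spec <- function(name = c("N450", "P300", "NSW"),
                               electrodes = NULL, window = NULL) {
  name <- match.arg(name)
  preset <- switch(name,
    N450 = list(electrodes = c("FC1", "FC2", "FCz", "C1", "C2", "Cz"),
                window = c(300, 500)),
    P300 = list(electrodes = c("Pz", "CP1", "CP2", "P1", "P2"),
                window = c(300, 800)),
    NSW = list(electrodes = c("AF3", "F3", "F5"),
               window = c(500, 3000)))
  structure(list(name = name,
                 electrodes = electrodes %||% preset$electrodes,
                 window = window %||% preset$window),
            class = "erp_component_spec")
}

#' Mean ERP component amplitude per condition
#'
#' Averages voltage over the component's electrode cluster, time window and
#' trials, separately per condition, for one participant's epochs.
#'
#' @param epochs an `epoch_set`.
#' @param spec an [erp_component_spec()].
#' @return data.frame `condition, amplitude` (uV).
#' @export
erp_amplitude <- function(epochs, spec) {
  miss <- setdiff(spec$electrodes, epochs$channel_names)
  .assert(length(miss) == 0,
          paste("missing electrodes:", paste(miss, collapse = ", ")))
  ci <- match(spec$electrodes, epochs$channel_names)
  ti <- time_window_idx(epochs$times, spec$window)
  .assert(length(ti) > 0, "component window outside epoch")
  per_trial <- apply(epochs$data[, ci, ti, drop = FALSE], 1, mean)
  out <- stats::aggregate(list(amplitude = per_trial),
                          by = list(condition = epochs$trial_table$condition),
                          FUN = mean)
  out[order(out$condition), , drop = FALSE]
}
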