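#' Normalize a GAW to the maximum peak of the first syllable
#'
#' Raw glottal areas (pixel units) are divided by the maximum area observed
#' within the first syllable of the recording, taken as the first
#' `syllable_fraction` of the total signal duration. After normalization the
#' largest cycle peak of the first syllable equals 1; later syllables may
#' exceed 1.
#'
#' @param gaw A raw (unfiltered, nonnegative) [gaw_signal()].
#' @param syllable_fraction Fraction of the signal duration treated as the
#'   first syllable. Default 0.4.
#' @return The normalized [gaw_signal()] (flag `normalized` set).
#' @export
normalize_gaw <- function(gaw, syllable_fraction = 0.4) {
  stopifnot(inherits(gaw, "gaw_signal"))
  if (isTRUE(attr(gaw, "filtered"))) {
    abort("normalize_gaw() expects the raw (unfiltered) signal.",
          class = "gawvot_error_input")
  }
  n_win <- max(1L, floor(nrow(gaw) * syllable_fraction))
  m <- max(gaw$area[seq_len(n_win)])
  if (!is.finite(m) || m <= 0) {
    abort("first-syllable window contains no positive area; cannot normalize.",
          class = "gawvot_error_degenerate")
  }
  restore_gaw(gaw, gaw, area = gaw$area / m, normalized = TRUE)
}

#' Estimate the fundamental frequency of a GAW
#'
#' The dominant oscillation frequency is estimated from the first
#' `window_ms` of the signal (default 180 ms) by autocorrelation of the
#' mean-removed window. The lag search is restricted to the physiological
#' band 50-500 Hz and the autocorrelation peak is refined by parabolic
#' interpolation, giving sub-sample lag resolution. A warning is raised if
#' the estimate lands on the search boundary.
#'
#' @param gaw A [gaw_signal()].
#' @param window_ms Analysis window length in ms from the signal start.
#' @return Fundamental frequency in Hz.
#' @export
estimate_f0 <- function(gaw, window_ms = 180) {
  stopifnot(inherits(gaw, "gaw_signal"))
  fps <- gaw_fps(gaw)
  n <- min(nrow(gaw), max(2L, round(window_ms / 1000 * fps)))
  x <- gaw$area[seq_len(n)]
  x <- x - mean(x)
  if (sum(x^2) == 0) {
    abort("signal has no oscillation in the analysis window.",
          class = "gawvot_error_estimation")
  }
  lag_min <- max(2L, floor(fps / 500))
  lag_max <- min(n - 2L, ceiling(fps / 50))
  if (lag_max <= lag_min) {
    abort("analysis window too short for f0 estimation (needs >= 2 cycles).",
          class = "gawvot_error_estimation")
  }
  ac <- acf(x, lag.max = lag_max, plot = FALSE, demean = FALSE)$acf[, 1, 1]
  lags <- lag_min:lag_max
  r <- ac[lags + 1L]
  k <- lags[which.max(r)]
  if (k == lag_min || k == lag_max) {
    warn("f0 estimate lies on the physiological search boundary [50, 500] Hz.")
  }
  # parabolic interpolation around the autocorrelation maximum
  if (k > lag_min && k < lag_max) {
    y0 <- ac[k]
    y1 <- ac[k + 1L]
    y2 <- ac[k + 2L]
    denom <- y0 - 2 * y1 + y2
    delta <- if (abs(denom) > .Machine$double.eps) 0.5 * (y0 - y2) / denom else 0
    delta <- max(-0.5, min(0.5, delta))
  } else {
    delta <- 0
  }
  fps / (k + delta)
}

#' Band-pass filter a GAW around its fundamental frequency
#'
#' Applies a fourth-order Butterworth band-pass (second-order low/high-pass
#' prototype) with corner frequencies `band * f0`, run forward-backward
#' (zero phase) so cycle-peak times are not displaced by group delay. The
#' high-pass side removes the DC offset; the low-pass side smooths
#' high-frequency segmentation artifacts. The signal is mirror-padded before
#' filtering to suppress edge transients.
#'
#' @param gaw A [gaw_signal()].
#' @param f0 Fundamental frequency in Hz; defaults to the stored estimate.
#' @param band Length-2 multipliers of `f0` for the pass band
#'   (default `c(0.7, 1.3)`).
#' @param order Overall band-pass order (must be even; default 4).
#' @return The filtered [gaw_signal()] (flag `filtered` set); values may be
#'   negative and the mean is removed by construction.
#' @export
bandpass_gaw <- function(gaw, f0 = gaw_f0(gaw), band = c(0.7, 1.3), order = 4L) {
  stopifnot(inherits(gaw, "gaw_signal"))
  fps <- gaw_fps(gaw)
  if (!is.finite(f0) || f0 <= 0) {
    abort("`f0` must be positive; estimate it first with estimate_f0().",
          class = "gawvot_error_config")
  }
  if (length(band) != 2 || band[1] <= 0 || band[2] <= band[1]) {
    abort("`band` must be increasing positive multipliers of f0.",
          class = "gawvot_error_config")
  }
  if (band[2] * f0 >= fps / 2) {
    abort("upper band edge reaches the Nyquist frequency.",
          class = "gawvot_error_config")
  }
  if (order %% 2 != 0 || order < 2) {
    abort("`order` must be an even integer >= 2.", class = "gawvot_error_config")
  }
  bf <- signal::butter(order / 2, band * f0 / (fps / 2), type = "pass")
  x <- gaw$area
  n <- length(x)
  # odd (point-symmetric) mirror padding, as in standard zero-phase practice
  npad <- min(n - 1L, max(12L, 10L * round(fps / f0)))
  head_pad <- 2 * x[1] - x[(npad + 1):2]
  tail_pad <- 2 * x[n] - x[(n - 1):(n - npad)]
  xp <- c(head_pad, x, tail_pad)
  yp <- signal::filtfilt(bf, xp)
  y <- yp[(npad + 1):(npad + n)]
  restore_gaw(gaw, gaw, area = y, filtered = TRUE, f0 = f0)
}
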