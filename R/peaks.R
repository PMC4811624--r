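#' Detect one peak per oscillation cycle of a GAW
#'
#' Cycle peaks are the fit substrate for the onset envelope. For unfiltered
#' signals, cycles are delimited by local minima of a lightly smoothed copy
#' of the signal (minimum separation half a period at `f0`); for band-pass
#' filtered signals, by negative-to-positive zero crossings. Within each
#' cycle the maximum of the raw signal is taken, with flat maxima resolved
#' to the earliest sample. Peaks smaller than `min_peak_frac` times the
#' signal maximum are discarded as noise.
#'
#' Each peak is annotated with `preceded_by_closure`: whether the
#' (unfiltered) signal dropped to `closure_epsilon` or below between the
#' previous peak and this one. For filtered signals this annotation is
#' inherited from the paired unfiltered signal supplied via
#' `closure_reference`; without a reference the flag is `NA`.
#'
#' @param gaw A [gaw_signal()] (normalized; filtered or unfiltered).
#' @param f0 Fundamental frequency in Hz; defaults to the stored estimate.
#' @param closure_epsilon Normalized-area threshold below which the glottis
#'   counts as closed. Default 0.005.
#' @param closure_reference For filtered signals, the paired unfiltered
#'   normalized [gaw_signal()] used to judge glottal closure.
#' @param min_peak_frac Peaks below this fraction of the signal maximum are
#'   dropped. Default 0.02.
#' @return A tibble of class `gaw_peaks` with columns `index` (sample),
#'   `time_ms`, `amplitude`, `preceded_by_closure`.
#' @export
detect_cycle_peaks <- function(gaw, f0 = gaw_f0(gaw), closure_epsilon = 0.005,
                               closure_reference = NULL, min_peak_frac = 0.02) {
  stopifnot(inherits(gaw, "gaw_signal"))
  if (!is.finite(f0) || f0 <= 0) {
    abort("`f0` must be known to delimit cycles; run estimate_f0() first.",
          class = "gawvot_error_config")
  }
  fps <- gaw_fps(gaw)
  x <- gaw$area
  n <- length(x)
  if (max(x) == min(x)) {
    abort("signal has no oscillation.", class = "gawvot_error_degenerate")
  }
  filtered <- isTRUE(attr(gaw, "filtered"))

  if (filtered) {
    cross <- which(x[-n] < 0 & x[-1] >= 0)
    bounds <- unique(c(1L, cross + 1L, n))
  } else {
    w <- max(3L, round(fps / (6 * f0)))
    if (w %% 2L == 0L) w <- w + 1L
    xs <- stats::filter(x, rep(1 / w, w), sides = 2)
    xs[is.na(xs)] <- x[is.na(xs)]
    xs <- as.numeric(xs)
    cand <- which(xs[2:(n - 1)] <= xs[1:(n - 2)] & xs[2:(n - 1)] < xs[3:n]) + 1L
    # enforce minimum separation of half a period, keeping deeper minima
    min_sep <- max(1L, round(0.5 * fps / f0))
    keep <- logical(length(cand))
    for (i in order(xs[cand])) {
      if (!any(keep & abs(cand - cand[i]) < min_sep)) keep[i] <- TRUE
    }
    bounds <- unique(sort(c(1L, cand[keep], n)))
  }
  if (length(bounds) < 2) {
    abort("no oscillation cycles found.", class = "gawvot_error_degenerate")
  }

  peak_idx <- integer(0)
  for (b in seq_len(length(bounds) - 1L)) {
    seg <- bounds[b]:bounds[b + 1L]
    peak_idx <- c(peak_idx, seg[which.max(x[seg])])  # which.max = earliest tie
  }
  peak_idx <- unique(peak_idx)
  floor_amp <- min_peak_frac * max(x)
  peak_idx <- peak_idx[x[peak_idx] > floor_amp]
  # a boundary sample can win a segment without being a true local maximum
  peak_idx <- peak_idx[vapply(peak_idx, function(i) {
    (i == 1L || x[i] >= x[i - 1L]) && (i == n || x[i] >= x[i + 1L])
  }, logical(1))]
  if (length(peak_idx) == 0) {
    abort("no oscillation cycles found.", class = "gawvot_error_degenerate")
  }

  ref <- if (filtered) closure_reference else gaw
  closed <- rep(NA, length(peak_idx))
  if (!is.null(ref)) {
    ref_x <- ref$area
    ref_t <- ref$time_ms
    pk_t <- gaw$time_ms[peak_idx]
    prev_t <- c(ref_t[1], pk_t[-length(pk_t)])
    closed <- vapply(seq_along(peak_idx), function(j) {
      sel <- ref_t >= prev_t[j] & ref_t < pk_t[j]
      any(ref_x[sel] <= closure_epsilon)
    }, logical(1))
  }

  out <- tibble(
    index = peak_idx,
    time_ms = gaw$time_ms[peak_idx],
    amplitude = x[peak_idx],
    preceded_by_closure = closed
  )
  class(out) <- c("gaw_peaks", class(out))
  attr(out, "fps") <- fps
  attr(out, "f0") <- f0
  attr(out, "filtered") <- filtered
  attr(out, "duration_ms") <- gaw_duration_ms(gaw)
  out
}

#' Time of first vocal-fold contact
#'
#' During the earliest onset cycles the vocal folds oscillate without
#' touching; the glottal area never reaches zero. The first contact is the
#' first sample at or below `closure_epsilon` that is followed later by a
#' reopening (a sample above the threshold). Absence of closure is a valid
#' outcome and returns `NA`.
#'
#' @param gaw An unfiltered, normalized [gaw_signal()].
#' @param closure_epsilon Normalized-area closure threshold. Default 0.005.
#' @return Time of first contact in ms, or `NA_real_` if the folds never touch.
#' @export
detect_first_contact <- function(gaw, closure_epsilon = 0.005) {
  stopifnot(inherits(gaw, "gaw_signal"))
  if (isTRUE(attr(gaw, "filtered"))) {
    abort("first contact is defined on the unfiltered signal.",
          class = "gawvot_error_input")
  }
  x <- gaw$area
  below <- which(x <= closure_epsilon)
  for (i in below) {
    if (i < length(x) && any(x[(i + 1):length(x)] > closure_epsilon)) {
      return(gaw$time_ms[i])
    }
  }
  NA_real_
}

#' Central moving average of cycle-peak amplitudes
#'
#' The saturation amplitude is derived from a centered moving average (cma)
#' of the cycle-peak amplitudes with a kernel of five peaks. Peaks not
#' preceded by glottal closure are excluded before averaging, so on a
#' typical onset with two open cycles the first cma value sits at the fifth
#' overall peak. The cma is only defined where the full kernel fits.
#'
#' @param peaks A `gaw_peaks` tibble from [detect_cycle_peaks()].
#' @param kernel Odd kernel size in peaks. Default 5.
#' @return A tibble with one row per cma value: `peak_row` (row of the
#'   center peak in `peaks`), `time_ms`, `cma`, and `window_last_row` (row
#'   of the last peak inside the kernel window).
#' @export
central_moving_average <- function(peaks, kernel = 5L) {
  stopifnot(inherits(peaks, "gaw_peaks"))
  k <- as.integer(kernel)
  if (k < 1L || k %% 2L == 0L) {
    abort("`kernel` must be a positive odd integer.", class = "gawvot_error_config")
  }
  eligible <- which(!vapply(peaks$preceded_by_closure, isFALSE, logical(1)))
  if (length(eligible) < k) {
    abort(sprintf("need at least %d closure-preceded peaks for the cma; got %d.",
                  k, length(eligible)),
          class = "gawvot_error_insufficient")
  }
  h <- (k - 1L) %/% 2L
  centers <- (1L + h):(length(eligible) - h)
  amp <- peaks$amplitude[eligible]
  tibble(
    peak_row = eligible[centers],
    time_ms = peaks$time_ms[eligible[centers]],
    cma = vapply(centers, function(j) mean(amp[(j - h):(j + h)]), numeric(1)),
    window_last_row = eligible[centers + h]
  )
}

#' Saturation amplitude of the first syllable
#'
#' The saturation amplitude `r_sat` is the mean oscillation amplitude during
#' sustained phonation, estimated as the maximum of the cycle-peak cma
#' within the first syllable (the first `syllable_fraction` of the signal
#' duration). The last peak of the maximizing cma window bounds the fit
#' domain: peaks beyond it belong to sustained phonation, not onset.
#'
#' @param peaks A `gaw_peaks` tibble.
#' @param cma Output of [central_moving_average()]; computed if missing.
#' @param syllable_fraction First-syllable fraction of the total duration.
#' @param kernel Kernel passed to [central_moving_average()] when `cma` is
#'   not supplied.
#' @return A list with `r_sat` (= `cma_max`), `cma_max`, `last_fit_peak_row`
#'   (row in `peaks` of the last peak in the maximizing window), and the
#'   `cma` table.
#' @export
saturation_amplitude <- function(peaks, cma = NULL, syllable_fraction = 0.4,
                                 kernel = 5L) {
  stopifnot(inherits(peaks, "gaw_peaks"))
  if (is.null(cma)) cma <- central_moving_average(peaks, kernel)
  t_max <- syllable_fraction * attr(peaks, "duration_ms")
  inside <- cma$time_ms < t_max
  if (!any(inside)) {
    abort("no cma value inside the first-syllable window.",
          class = "gawvot_error_insufficient")
  }
  cw <- cma[inside, , drop = FALSE]
  j <- which.max(cw$cma)
  list(
    r_sat = cw$cma[j],
    cma_max = cw$cma[j],
    last_fit_peak_row = cw$window_last_row[j],
    cma = cma
  )
}

#' Select the peaks used for envelope fitting
#'
#' For unfiltered GAWs only peaks after the first vocal-fold contact enter
#' the fit; for filtered GAWs all peaks are used, including those before
#' first contact. In both cases the series ends at the last peak of the
#' maximizing cma window. At least three peaks are required.
#'
#' @param peaks A `gaw_peaks` tibble.
#' @param variant `"unfiltered"` or `"filtered"`.
#' @param first_contact_ms Time of first vocal-fold contact (ms); required
#'   for the unfiltered rule. `NA` means the folds never touch, which makes
#'   the unfiltered fit impossible.
#' @param last_fit_peak_row Row index of the last fit peak (from
#'   [saturation_amplitude()]).
#' @return The selected subset of `peaks` (still a `gaw_peaks` tibble).
#' @export
select_fit_peaks <- function(peaks, variant = c("unfiltered", "filtered"),
                             first_contact_ms = NA_real_,
                             last_fit_peak_row = nrow(peaks)) {
  stopifnot(inherits(peaks, "gaw_peaks"))
  variant <- match.arg(variant)
  rows <- seq_len(min(last_fit_peak_row, nrow(peaks)))
  if (variant == "unfiltered") {
    if (is.na(first_contact_ms)) {
      abort("no vocal-fold contact: unfiltered fitting requires closure.",
            class = "gawvot_error_insufficient")
    }
    rows <- rows[peaks$time_ms[rows] > first_contact_ms]
  }
  if (length(rows) < 3L) {
    abort(sprintf("need at least 3 fit peaks; got %d.", length(rows)),
          class = "gawvot_error_insufficient")
  }
  out <- peaks[rows, ]
  class(out) <- c("gaw_peaks", setdiff(class(out), "gaw_peaks"))
  for (a in c("fps", "f0", "filtered", "duration_ms")) {
    attr(out, a) <- attr(peaks, a)
  }
  out
}
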