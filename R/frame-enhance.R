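#' Image enhancement for high-speed laryngeal frames
#'
#' Three per-frame operations improve brightness and contrast of high-speed
#' endoscopic frames ahead of glottis segmentation: (1) stretching the
#' grey-scale values to the full 0-255 range, which also suppresses the slow
#' lamp flicker because each frame is rescaled independently; (2) a linear
#' spatial low-pass (box) filter against fibre-optic interference patterns;
#' (3) clipping off the upper part of the grey-scale range and restretching
#' the remainder, which darkens the glottis relative to the tissue.
#'
#' All operations work on plain numeric matrices with intensities in
#' \[0, 255\] and apply round-half-up integer quantization to their output.
#'
#' @param frame A numeric matrix of grey-scale intensities in \[0, 255\].
#' @name frame_enhance
NULL

round_half_up <- function(x) floor(x + 0.5)

check_frame <- function(frame) {
  if (!is.matrix(frame) || length(frame) == 0 || !is.numeric(frame)) {
    abort("`frame` must be a nonempty numeric matrix.", class = "gawvot_error_input")
  }
  if (any(frame < 0) || any(frame > 255)) {
    abort("frame intensities must lie in [0, 255].", class = "gawvot_error_input")
  }
  invisible(frame)
}

#' @describeIn frame_enhance Linearly map intensities so the frame spans the
#'   full grey scale: minimum to 0, maximum to 255. Constant frames are
#'   returned unchanged (there is no range to stretch).
#' @export
stretch_grayscale <- function(frame) {
  check_frame(frame)
  lo <- min(frame)
  hi <- max(frame)
  if (hi == lo) {
    return(frame)
  }
  out <- (frame - lo) * (255 / (hi - lo))
  out[] <- round_half_up(out)
  out
}

#' @describeIn frame_enhance Box (mean) filter with reflective borders; the
#'   simplest linear spatial low-pass. `kernel_size` must be odd and >= 1;
#'   size 1 is the identity.
#' @param kernel_size Odd integer edge length of the square mean kernel.
#' @export
spatial_lowpass <- function(frame, kernel_size = 3L) {
  check_frame(frame)
  k <- as.integer(kernel_size)
  if (length(k) != 1 || is.na(k) || k < 1L || k %% 2L == 0L) {
    abort("`kernel_size` must be a positive odd integer.",
          class = "gawvot_error_config")
  }
  if (k == 1L) {
    return(frame)
  }
  h <- (k - 1L) %/% 2L
  pad_reflect <- function(m, h) {
    nr <- nrow(m)
    nc <- ncol(m)
    ridx <- c(rev(seq_len(min(h, nr - 1)) + 1L), seq_len(nr),
              nr - seq_len(min(h, nr - 1)))
    # if the frame is smaller than the half-kernel, clamp to edge
    ridx <- pmin(pmax(c(rep(1L, max(0L, h - nr + 1L)), ridx,
                        rep(nr, max(0L, h - nr + 1L))), 1L), nr)
    cidx <- c(rev(seq_len(min(h, nc - 1)) + 1L), seq_len(nc),
              nc - seq_len(min(h, nc - 1)))
    cidx <- pmin(pmax(c(rep(1L, max(0L, h - nc + 1L)), cidx,
                        rep(nc, max(0L, h - nc + 1L))), 1L), nc)
    m[ridx, cidx, drop = FALSE]
  }
  p <- pad_reflect(frame, h)
  # separable box mean: running sums over rows, then columns
  run_mean <- function(m, k) {
    cs <- apply(m, 2, cumsum)
    cs <- rbind(0, cs)
    (cs[(k + 1):nrow(cs), , drop = FALSE] -
        cs[1:(nrow(cs) - k), , drop = FALSE]) / k
  }
  out <- run_mean(p, k)
  out <- t(run_mean(t(out), k))
  out[] <- round_half_up(out)
  storage.mode(out) <- "double"
  stopifnot(all(dim(out) == dim(frame)))
  out
}

#' @describeIn frame_enhance Saturate intensities above
#'   `(1 - clip_fraction) * 255` to that ceiling, then linearly restretch
#'   `[0, ceiling]` to `[0, 255]`. The default clips the upper half of the
#'   grey-scale range.
#' @param clip_fraction Fraction of the upper grey-scale range to clip,
#'   strictly between 0 and 1.
#' @export
clip_and_restretch <- function(frame, clip_fraction = 0.5) {
  check_frame(frame)
  if (!is.numeric(clip_fraction) || length(clip_fraction) != 1 ||
      !is.finite(clip_fraction) || clip_fraction <= 0 || clip_fraction >= 1) {
    abort("`clip_fraction` must lie strictly between 0 and 1.",
          class = "gawvot_error_config")
  }
  ceiling_val <- (1 - clip_fraction) * 255
  out <- pmin(frame, ceiling_val) * (255 / ceiling_val)
  out[] <- round_half_up(out)
  out
}

#' Enhance a stack of high-speed frames
#'
#' Applies [stretch_grayscale()], [spatial_lowpass()] and
#' [clip_and_restretch()] in order to every frame of a stack (a list of
#' equal-sized intensity matrices).
#'
#' @param frames List of numeric intensity matrices (one per video frame).
#' @param kernel_size Passed to [spatial_lowpass()].
#' @param clip_fraction Passed to [clip_and_restretch()].
#' @return List of enhanced frames, same length and shapes as the input.
#' @export
enhance_frames <- function(frames, kernel_size = 3L, clip_fraction = 0.5) {
  if (!is.list(frames) || length(frames) == 0) {
    abort("`frames` must be a nonempty list of matrices.",
          class = "gawvot_error_input")
  }
  dims <- unique(lapply(frames, dim))
  if (length(dims) != 1) {
    abort("all frames must have the same shape.", class = "gawvot_error_input")
  }
  lapply(frames, function(f) {
    clip_and_restretch(
      spatial_lowpass(stretch_grayscale(f), kernel_size),
      clip_fraction
    )
  })
}
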