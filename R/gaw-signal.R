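#' Construct a glottal area waveform (GAW) signal
#'
#' A GAW is the glottal area per video frame, one sample per frame. The
#' object is a tibble with columns `time_ms` and `area`, carrying the frame
#' rate and processing-state flags as attributes so the signal can be piped
#' through the preprocessing steps.
#'
#' @param area Numeric vector of glottal areas (pixel units if raw,
#'   dimensionless once normalized). Raw signals must be nonnegative;
#'   band-pass filtered signals may be negative.
#' @param fps Sampling rate in frames per second (Hz). Must be positive.
#' @param time_ms Optional time stamps in ms; defaults to `(0:(n-1))/fps * 1000`.
#' @param normalized Logical flag: has the signal been normalized to the
#'   maximum cycle peak of the first syllable?
#' @param filtered Logical flag: is this the band-pass filtered variant?
#' @param f0 Fundamental frequency in Hz, if known.
#'
#' @return A tibble of class `gaw_signal` with columns `time_ms`, `area`.
#' @seealso [read_gaw()], [normalize_gaw()], [bandpass_gaw()]
#' @export
#' @examples
#' t <- seq(0, 0.1, by = 1 / 8000)
#' gaw_signal(pmax(0, sin(2 * pi * 200 * t)), fps = 8000)
gaw_signal <- function(area, fps, time_ms = NULL, normalized = FALSE,
                       filtered = FALSE, f0 = NULL) {
  if (!is.numeric(area) || length(area) == 0) {
    abort("`area` must be a nonempty numeric vector.", class = "gawvot_error_input")
  }
  if (!is.numeric(fps) || length(fps) != 1 || !is.finite(fps) || fps <= 0) {
    abort("`fps` must be a single positive number (Hz).", class = "gawvot_error_config")
  }
  if (!filtered && any(area < 0, na.rm = TRUE)) {
    abort("raw (unfiltered) GAW areas must be nonnegative.",
          class = "gawvot_error_input")
  }
  if (is.null(time_ms)) {
    time_ms <- (seq_along(area) - 1) / fps * 1000
  }
  out <- tibble(time_ms = as.numeric(time_ms), area = as.numeric(area))
  class(out) <- c("gaw_signal", class(out))
  attr(out, "fps") <- as.numeric(fps)
  attr(out, "normalized") <- isTRUE(normalized)
  attr(out, "filtered") <- isTRUE(filtered)
  attr(out, "f0") <- if (is.null(f0)) NA_real_ else as.numeric(f0)
  out
}

#' @export
print.gaw_signal <- function(x, ...) {
  fps <- gaw_fps(x)
  cat(sprintf(
    "<gaw_signal> %d samples @ %g fps (%.1f ms)%s%s%s\n",
    nrow(x), fps, nrow(x) / fps * 1000,
    if (isTRUE(attr(x, "normalized"))) ", normalized" else "",
    if (isTRUE(attr(x, "filtered"))) ", filtered" else "",
    if (is.finite(gaw_f0(x))) sprintf(", f0 = %.1f Hz", gaw_f0(x)) else ""
  ))
  NextMethod()
}

#' Accessors for GAW signal metadata
#'
#' @param gaw A [gaw_signal()].
#' @return `gaw_fps()` the frame rate in Hz; `gaw_f0()` the stored
#'   fundamental frequency in Hz (`NA` until estimated); `gaw_duration_ms()`
#'   the total duration in ms.
#' @export
gaw_fps <- function(gaw) attr(gaw, "fps")

#' @rdname gaw_fps
#' @export
gaw_f0 <- function(gaw) {
  f0 <- attr(gaw, "f0")
  if (is.null(f0)) NA_real_ else f0
}

#' @rdname gaw_fps
#' @export
gaw_duration_ms <- function(gaw) nrow(gaw) / gaw_fps(gaw) * 1000

# keep class + attributes through dplyr-style subsetting used internally
restore_gaw <- function(new, template, area = NULL, normalized = NULL,
                        filtered = NULL, f0 = NULL) {
  gaw_signal(
    area = if (is.null(area)) new$area else area,
    fps = gaw_fps(template),
    time_ms = new$time_ms,
    normalized = if (is.null(normalized)) attr(template, "normalized") else normalized,
    filtered = if (is.null(filtered)) attr(template, "filtered") else filtered,
    f0 = if (is.null(f0)) gaw_f0(template) else f0
  )
}

#' Read a GAW from delimited text
#'
#' Accepts either a two-column file (time in ms, area) or a one-column file
#' of areas with the frame rate supplied via `fps`. Delimiters may be
#' whitespace, comma, semicolon or tab; a single header line is detected and
#' skipped. For two-column files the frame rate is inferred from the median
#' time step; sampling jitter beyond 1% of that step is rejected.
#'
#' @param path Path to the text file.
#' @param fps Frame rate override in Hz. Required for one-column files.
#' @return A [gaw_signal()].
#' @export
read_gaw <- function(path, fps = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "gawvot_error_input")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    abort("empty GAW file.", class = "gawvot_error_input")
  }
  split_row <- function(l) strsplit(trimws(l), "[,;\t ]+")[[1]]
  first <- suppressWarnings(as.numeric(split_row(lines[1])))
  start <- if (any(is.na(first))) 2L else 1L
  if (start > length(lines)) {
    abort("GAW file contains a header but no data rows.", class = "gawvot_error_input")
  }
  rows <- lapply(lines[start:length(lines)], split_row)
  ncol <- unique(lengths(rows))
  if (length(ncol) != 1 || !ncol %in% c(1L, 2L)) {
    bad <- which(lengths(rows) != lengths(rows)[1])[1]
    abort(sprintf("inconsistent number of columns at line %d.", start + bad - 1L),
          class = "gawvot_error_parse")
  }
  vals <- suppressWarnings(vapply(rows, function(r) as.numeric(r), numeric(ncol)))
  vals <- if (ncol == 1L) matrix(vals, ncol = 1) else t(vals)
  bad <- which(apply(vals, 1, function(r) any(is.na(r))))
  if (length(bad) > 0) {
    abort(sprintf("non-numeric value at line %d of %s.", start + bad[1] - 1L, path),
          class = "gawvot_error_parse")
  }
  if (ncol == 2L) {
    dt <- diff(vals[, 1])
    mdt <- median(dt)
    if (mdt <= 0 || any(abs(dt - mdt) > 0.01 * mdt)) {
      abort("nonuniform sampling: time steps deviate by more than 1%.",
            class = "gawvot_error_parse")
    }
    inferred_fps <- 1000 / mdt
    gaw_signal(vals[, 2], fps = if (is.null(fps)) inferred_fps else fps,
               time_ms = vals[, 1])
  } else {
    if (is.null(fps)) {
      abort("one-column GAW file requires `fps`.", class = "gawvot_error_config")
    }
    gaw_signal(vals[, 1], fps = fps)
  }
}

#' Write a GAW to delimited text
#'
#' Writes a two-column (time_ms, area) tab-separated file with a header.
#'
#' @param gaw A [gaw_signal()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gaw <- function(gaw, path) {
  utils::write.table(
    data.frame(time_ms = gaw$time_ms, area = gaw$area),
    path, sep = "\t", row.names = FALSE, quote = FALSE
  )
  invisible(path)
}
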