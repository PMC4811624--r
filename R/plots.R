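#' Plot a GAW signal
#'
#' @param object A [gaw_signal()].
#' @param peaks Optional `gaw_peaks` tibble to overlay.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gaw_signal <- function(object, peaks = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time_ms, y = .data$area)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(
      x = "time (ms)",
      y = if (isTRUE(attr(object, "normalized"))) "normalized glottal area"
          else "glottal area",
      title = paste0("GAW", if (isTRUE(attr(object, "filtered"))) " (band-pass filtered)")
    )
  if (!is.null(peaks)) {
    p <- p + ggplot2::geom_point(
      data = peaks,
      ggplot2::aes(x = .data$time_ms, y = .data$amplitude,
                   colour = .data$preceded_by_closure),
      size = 1.2
    ) +
      ggplot2::labs(colour = "preceded by closure")
  }
  p
}

#' Plot an envelope fit over its peaks
#'
#' Shows the cycle peaks used for fitting, the fitted envelope, the
#' polynomial supporting point (if any), and optional VOT threshold lines.
#'
#' @param object An `envelope_fit`.
#' @param r_sat Saturation amplitude for threshold lines; omitted if `NULL`.
#' @param definition A [vot_definition()] for the threshold lines.
#' @param ... Unused.
#' @return A ggplot. Times are relative to the first fit peak.
#' @export
autoplot.envelope_fit <- function(object, r_sat = NULL,
                                  definition = vot_definition("VOT67"), ...) {
  pk <- tibble(time_ms = object$fit_peaks$time_ms - object$t0_ms,
               amplitude = object$fit_peaks$amplitude)
  t_lo <- if (!is.null(object$supporting_point)) object$supporting_point$time_ms
          else min(pk$time_ms)
  grid <- tibble(time_ms = seq(t_lo, max(pk$time_ms), length.out = 400))
  grid$fit <- predict(object, grid$time_ms)
  p <- ggplot2::ggplot(pk, ggplot2::aes(x = .data$time_ms, y = .data$amplitude)) +
    ggplot2::geom_point(size = 1.4) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$fit),
                       colour = "steelblue") +
    ggplot2::labs(x = "time from first fit peak (ms)", y = "normalized amplitude",
                  title = sprintf("%s envelope fit (RMSE %.3f)",
                                  object$family, object$rmse))
  if (!is.null(object$supporting_point)) {
    p <- p + ggplot2::annotate("point", x = object$supporting_point$time_ms,
                               y = 0, shape = 4, size = 2.5)
  }
  if (!is.null(r_sat)) {
    p <- p + ggplot2::geom_hline(
      yintercept = r_sat * c(definition$lower_fraction, definition$upper_fraction),
      linetype = "dashed", colour = "grey40"
    )
  }
  p
}

#' Reliability overview of a corpus evaluation
#'
#' Bar chart of reliability (percent of recordings with a computable VOT)
#' per fit family, faceted by signal variant and VOT definition.
#'
#' @param rows Output of [evaluate_corpus()].
#' @return A ggplot.
#' @export
plot_corpus_reliability <- function(rows) {
  ggplot2::ggplot(rows, ggplot2::aes(x = .data$family, y = .data$reliability)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_grid(.data$definition ~ .data$variant) +
    ggplot2::coord_cartesian(ylim = c(0, 100)) +
    ggplot2::labs(x = "fit family", y = "reliability (%)")
}
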