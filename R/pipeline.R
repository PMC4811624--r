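#' Pipeline configuration
#'
#' Collects every tunable of the GAW-to-VOT pipeline with defaults matching
#' the standard acquisition and analysis settings: 8000 fps recordings, the
#' first syllable spanning the first 40% of the signal, a fourth-order
#' Butterworth band-pass from 0.7 to 1.3 times the fundamental frequency,
#' f0 estimated over the first 180 ms, a five-peak cma kernel, and a
#' normalized closure threshold of 0.005.
#'
#' @param fps Frame rate in Hz for signals lacking a time column.
#' @param syllable_fraction First-syllable fraction of the signal duration.
#' @param f0_window_ms Window for f0 estimation, in ms.
#' @param band Band-pass corner multipliers of f0.
#' @param filter_order Overall Butterworth band-pass order (even).
#' @param closure_epsilon Normalized-area closure threshold.
#' @param cma_kernel Central-moving-average kernel, in peaks.
#' @param min_peak_frac Noise floor for peak detection, as a fraction of
#'   the signal maximum.
#' @param families Fit families to run, from
#'   `c("M_a", "M_as", "M_asr", "P2", "P3", "P4")`.
#' @param variants Signal variants: `"GAW_o"` (unfiltered) and/or `"GAW_f"`
#'   (band-pass filtered).
#' @param definitions VOT definitions: `"VOT67"` and/or `"VOT90"`. VOT90
#'   applies to polynomial families only.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(fps = 8000, syllable_fraction = 0.4,
                            f0_window_ms = 180, band = c(0.7, 1.3),
                            filter_order = 4L, closure_epsilon = 0.005,
                            cma_kernel = 5L, min_peak_frac = 0.02,
                            families = c("M_a", "M_as", "M_asr",
                                         "P2", "P3", "P4"),
                            variants = c("GAW_o", "GAW_f"),
                            definitions = c("VOT67", "VOT90")) {
  families <- match.arg(families, several.ok = TRUE)
  variants <- match.arg(variants, several.ok = TRUE)
  definitions <- match.arg(definitions, several.ok = TRUE)
  structure(
    list(fps = fps, syllable_fraction = syllable_fraction,
         f0_window_ms = f0_window_ms, band = band,
         filter_order = as.integer(filter_order),
         closure_epsilon = closure_epsilon, cma_kernel = as.integer(cma_kernel),
         min_peak_frac = min_peak_frac, families = families,
         variants = variants, definitions = definitions),
    class = "pipeline_config"
  )
}

is_m_family <- function(family) startsWith(family, "M_")

#' Compute a VOT from a fitted envelope under a named definition
#'
#' Dispatches to the reciprocal rule for M-family fits (VOT67 only; for
#' the Hopf-bifurcation envelope the growth rate is the reciprocal of
#' VOT67, and VOT90 is not defined) and to threshold crossings for
#' polynomial fits.
#'
#' @param fit An `envelope_fit`.
#' @param definition `"VOT67"` or `"VOT90"`.
#' @param r_sat Measured saturation amplitude (needed for polynomial fits).
#' @return A one-row VOT tibble; see [vot_from_crossings()].
#' @export
compute_vot <- function(fit, definition = "VOT67", r_sat = NULL) {
  if (is_m_family(fit$family)) {
    if (definition == "VOT90") {
      abort(paste("VOT90 is not defined for M-family fits: the growth rate",
                  "is the reciprocal of VOT67, and only VOT67 is computed."),
            class = "gawvot_error_config")
    }
    vot_reciprocal_M(fit)
  } else {
    vot_from_crossings(fit, r_sat = r_sat,
                       definition = vot_definition(definition))
  }
}

#' Run the full GAW-to-VOT pipeline on one recording
#'
#' Normalizes the raw GAW to the first-syllable maximum, estimates f0,
#' derives the band-pass filtered variant, detects cycle peaks and first
#' vocal-fold contact, computes the saturation amplitude from the
#' cycle-peak cma, selects the fit peaks per variant rule (unfiltered:
#' post-contact peaks only; filtered: all peaks) and fits each requested
#' envelope family, then evaluates each requested VOT definition.
#' Stage failures for a family are recorded in the report's `note` column
#' rather than aborting the run.
#'
#' @param gaw A raw [gaw_signal()] or a path readable by [read_gaw()].
#' @param config A [pipeline_config()].
#' @return A `gaw_report`: list with `f0`, `first_contact_ms`, per-variant
#'   `r_sat` and `r0`, the fitted objects in `fits`, and a `summary` tibble
#'   (one row per family x variant x definition) with `vot_ms`,
#'   `computable`, `rmse`, `converged`, `n_peaks`, `note`. `computable`
#'   requires both a located VOT and a converged fit.
#' @export
run_pipeline <- function(gaw, config = pipeline_config()) {
  if (is.character(gaw)) gaw <- read_gaw(gaw, fps = config$fps)
  stopifnot(inherits(gaw, "gaw_signal"))
  if (nrow(gaw) == 0 || all(gaw$area == 0)) {
    abort("degenerate signal: no glottal activity.",
          class = "gawvot_error_degenerate")
  }
  norm <- if (isTRUE(attr(gaw, "normalized"))) gaw else {
    normalize_gaw(gaw, config$syllable_fraction)
  }
  f0 <- estimate_f0(norm, config$f0_window_ms)
  gaw_f <- bandpass_gaw(norm, f0 = f0, band = config$band,
                        order = config$filter_order)
  first_contact <- detect_first_contact(norm, config$closure_epsilon)

  signals <- list(GAW_o = norm, GAW_f = gaw_f)
  fits <- list()
  rows <- list()
  info <- list(r_sat = c(GAW_o = NA_real_, GAW_f = NA_real_),
               r0 = c(GAW_o = NA_real_, GAW_f = NA_real_))

  for (variant in config$variants) {
    prep <- tryCatch({
      pk <- detect_cycle_peaks(
        signals[[variant]], f0 = f0,
        closure_epsilon = config$closure_epsilon,
        closure_reference = if (variant == "GAW_f") norm else NULL,
        min_peak_frac = config$min_peak_frac
      )
      sat <- saturation_amplitude(pk, syllable_fraction = config$syllable_fraction,
                                  kernel = config$cma_kernel)
      fp <- select_fit_peaks(
        pk, variant = if (variant == "GAW_f") "filtered" else "unfiltered",
        first_contact_ms = first_contact,
        last_fit_peak_row = sat$last_fit_peak_row
      )
      list(peaks = pk, sat = sat, fit_peaks = fp)
    }, error = function(e) e)

    for (family in config$families) {
      defs <- config$definitions
      if (is_m_family(family)) defs <- intersect(defs, "VOT67")
      if (inherits(prep, "error")) {
        for (d in defs) {
          rows[[length(rows) + 1L]] <- tibble(
            variant = variant, family = family, definition = d,
            vot_ms = NA_real_, computable = FALSE, rmse = NA_real_,
            converged = NA, n_peaks = NA_integer_,
            note = conditionMessage(prep)
          )
        }
        next
      }
      r_sat <- prep$sat$r_sat
      r0 <- prep$fit_peaks$amplitude[1]
      info$r_sat[[variant]] <- r_sat
      info$r0[[variant]] <- r0
      fit <- tryCatch({
        if (is_m_family(family)) {
          fit_envelope_M(prep$fit_peaks, variant = sub("^M_", "", family),
                         r0 = r0, r_sat = r_sat)
        } else {
          fit_envelope_poly(prep$fit_peaks,
                            order = as.integer(sub("^P", "", family)),
                            cycle_period_ms = 1000 / f0)
        }
      }, error = function(e) e)
      if (inherits(fit, "error")) {
        for (d in defs) {
          rows[[length(rows) + 1L]] <- tibble(
            variant = variant, family = family, definition = d,
            vot_ms = NA_real_, computable = FALSE, rmse = NA_real_,
            converged = NA, n_peaks = nrow(prep$fit_peaks),
            note = conditionMessage(fit)
          )
        }
        next
      }
      fits[[paste(variant, family, sep = ".")]] <- fit
      for (d in defs) {
        v <- compute_vot(fit, definition = d, r_sat = r_sat)
        rows[[length(rows) + 1L]] <- tibble(
          variant = variant, family = family, definition = d,
          vot_ms = v$vot_ms,
          computable = v$computable && fit$converged,
          rmse = fit$rmse, converged = fit$converged,
          n_peaks = nrow(fit$fit_peaks), note = NA_character_
        )
      }
    }
  }

  structure(
    list(f0 = f0, first_contact_ms = first_contact,
         r_sat = info$r_sat, r0 = info$r0,
         signals = signals, fits = fits,
         summary = dplyr::bind_rows(rows), config = config),
    class = "gaw_report"
  )
}

#' @export
print.gaw_report <- function(x, ...) {
  cat(sprintf("<gaw_report> f0 = %.1f Hz, first contact = %s ms\n",
              x$f0,
              if (is.na(x$first_contact_ms)) "none"
              else sprintf("%.2f", x$first_contact_ms)))
  print(x$summary)
  invisible(x)
}

#' @export
tidy.gaw_report <- function(x, ...) x$summary

#' @export
glance.gaw_report <- function(x, ...) {
  tibble(
    f0 = x$f0,
    first_contact_ms = x$first_contact_ms,
    r_sat_GAW_o = unname(x$r_sat["GAW_o"]),
    r_sat_GAW_f = unname(x$r_sat["GAW_f"]),
    n_computable = sum(x$summary$computable),
    n_rows = nrow(x$summary)
  )
}
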