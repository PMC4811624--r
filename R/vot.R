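#' Voice onset time definitions
#'
#' Two threshold-pair definitions of the voice onset interval are in use:
#' `VOT67` measures the time the envelope needs to grow from 32.2% to 67.8%
#' of the saturation amplitude; `VOT90` from 5% to 90%.
#'
#' @param name `"VOT67"` or `"VOT90"`.
#' @return A list with `name`, `lower_fraction`, `upper_fraction`.
#' @export
#' @examples
#' vot_definition("VOT67")
vot_definition <- function(name = c("VOT67", "VOT90")) {
  name <- match.arg(name)
  if (name == "VOT67") {
    list(name = "VOT67", lower_fraction = 0.322, upper_fraction = 0.678)
  } else {
    list(name = "VOT90", lower_fraction = 0.05, upper_fraction = 0.90)
  }
}

vot_result_row <- function(definition, t_lower, t_upper, computable, method) {
  tibble(
    definition = definition,
    t_lower_ms = t_lower,
    t_upper_ms = t_upper,
    vot_ms = if (computable) t_upper - t_lower else NA_real_,
    computable = computable,
    method = method
  )
}

#' Voice onset time from envelope threshold crossings
#'
#' Locates the first time the fitted envelope reaches the lower threshold
#' fraction of the saturation amplitude and the first later time it reaches
#' the upper fraction; the VOT is the difference. Times are in the fit
#' frame (`t = 0` at the first fit peak). Non-computability — the envelope
#' never reaching a threshold inside the search domain — is a valid
#' outcome, not an error; it is what the corpus-level reliability counts.
#'
#' For polynomial fits the search domain is the fitted data range, from the
#' supporting point to the last fit peak: polynomial behaviour beyond the
#' data is extrapolation and is not trusted. For M-family fits the envelope
#' is monotone and analytic on the whole axis, so crossings are found
#' wherever they lie.
#'
#' @param fit An `envelope_fit`.
#' @param r_sat Saturation amplitude the thresholds refer to. Defaults to
#'   the fit's own `r_sat` parameter for M-family fits (this is what makes
#'   the reciprocal rule hold); polynomial fits require the measured value.
#' @param definition A [vot_definition()].
#' @param search_domain Optional length-2 override of the search interval
#'   (ms, fit frame).
#' @param tol_ms Root-location tolerance in ms. Default `1e-4`.
#' @return A one-row tibble: `definition`, `t_lower_ms`, `t_upper_ms`,
#'   `vot_ms`, `computable`, `method`.
#' @export
vot_from_crossings <- function(fit, r_sat = NULL,
                               definition = vot_definition("VOT67"),
                               search_domain = NULL, tol_ms = 1e-4) {
  stopifnot(inherits(fit, "envelope_fit"))
  is_m <- startsWith(fit$family, "M_")
  if (is.null(r_sat)) {
    if (!is_m) {
      abort("polynomial fits need the measured `r_sat` for the thresholds.",
            class = "gawvot_error_config")
    }
    r_sat <- fit$params$r_sat
  }
  lo <- definition$lower_fraction * r_sat
  hi <- definition$upper_fraction * r_sat

  if (is_m) {
    p <- fit$params
    # M is strictly increasing with range (0, p$r_sat): a threshold is
    # crossed iff it lies below the asymptote
    if (hi >= p$r_sat || lo >= p$r_sat) {
      return(vot_result_row(definition$name, NA_real_, NA_real_, FALSE, "crossing"))
    }
    xi <- (p$r0 / p$r_sat)^2
    find <- function(thr) {
      guess <- m_crossing_time_ms(p$a, xi, thr / p$r_sat)
      stats::uniroot(function(t) predict(fit, t) - thr,
                     interval = guess + c(-1, 1) * max(1, 2000 / p$a),
                     extendInt = "upX", tol = tol_ms)$root
    }
    t_lo <- find(lo)
    t_hi <- find(hi)
    return(vot_result_row(definition$name, t_lo, t_hi, TRUE, "crossing"))
  }

  if (is.null(search_domain)) {
    t_start <- if (!is.null(fit$supporting_point)) fit$supporting_point$time_ms else 0
    t_end <- max(fit$fit_peaks$time_ms) - fit$t0_ms
    search_domain <- c(t_start, t_end)
  }
  grid <- seq(search_domain[1], search_domain[2], length.out = 4001L)
  f <- predict(fit, grid)

  # a threshold counts as reached only when the envelope crosses it upward
  # from below inside the domain; starting above it is the failure mode of
  # polynomials rising towards early times
  locate_up <- function(from_idx, thr) {
    cross <- which(f[-length(f)] < thr & f[-1] >= thr)
    cross <- cross[cross >= from_idx]
    if (length(cross) == 0) return(NA_real_)
    i <- cross[1]
    stats::uniroot(function(t) predict(fit, t) - thr,
                   interval = c(grid[i], grid[i + 1L]), tol = tol_ms)$root
  }
  t_lo <- locate_up(1L, lo)
  if (is.na(t_lo)) {
    return(vot_result_row(definition$name, NA_real_, NA_real_, FALSE, "crossing"))
  }
  i_lo <- max(1L, findInterval(t_lo, grid))
  t_hi <- locate_up(i_lo, hi)
  if (is.na(t_hi) || t_hi <= t_lo) {
    return(vot_result_row(definition$name, t_lo, NA_real_, FALSE, "crossing"))
  }
  vot_result_row(definition$name, t_lo, t_hi, TRUE, "crossing")
}

#' VOT67 of an M-family fit via the reciprocal rule
#'
#' For the Hopf-bifurcation envelope the growth rate `a` is the reciprocal
#' of the 32.2-67.8% onset time, so `VOT67 = 1000/a` ms. M-family fits
#' report VOT67 this way (the closed-form crossing interval, 0.9977/a,
#' agrees within 0.23% and is stored in `t_lower_ms`/`t_upper_ms` for
#' cross-checking). VOT90 is not defined for M-family fits.
#'
#' @param fit An M-family `envelope_fit`, or a growth rate `a` in 1/s.
#' @return A one-row tibble as in [vot_from_crossings()], with
#'   `method = "reciprocal"` and `vot_ms = 1000/a`.
#' @export
vot_reciprocal_M <- function(fit) {
  if (inherits(fit, "envelope_fit")) {
    if (!startsWith(fit$family, "M_")) {
      abort("the reciprocal rule applies to M-family fits only.",
            class = "gawvot_error_config")
    }
    a <- fit$params$a
    xi <- (fit$params$r0 / fit$params$r_sat)^2
  } else {
    a <- fit
    xi <- NULL
  }
  if (!is.finite(a) || a <= 0) {
    abort("`a` must be positive.", class = "gawvot_error_parameter")
  }
  t_lo <- if (is.null(xi)) NA_real_ else m_crossing_time_ms(a, xi, 0.322)
  t_hi <- if (is.null(xi)) NA_real_ else m_crossing_time_ms(a, xi, 0.678)
  out <- vot_result_row("VOT67", t_lo, t_hi, TRUE, "reciprocal")
  out$vot_ms <- 1000 / a
  out
}
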