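#' Hopf-bifurcation envelope of oscillation onset
#'
#' The amplitude envelope of vocal-fold oscillation onset follows the
#' normal form of a supercritical Hopf bifurcation,
#' \deqn{M(t) = r_0 \left[(1-\xi)e^{-2at} + \xi\right]^{-1/2}, \qquad
#'       \xi = (r_0/r_{sat})^2,}
#' which grows from \eqn{M(0) = r_0} towards the saturation amplitude
#' \eqn{r_{sat}} as \eqn{t \to \infty} and decays to zero as
#' \eqn{t \to -\infty}. The growth-rate parameter `a` (1/s) is the
#' reciprocal of the 32.2-67.8% onset time to within 0.23%.
#'
#' @param t_ms Time in ms (vectorized); the envelope anchors `M(0) = r0`.
#' @param a Growth rate in 1/s.
#' @param r0 Amplitude of the first oscillation cycle (normalized units);
#'   must satisfy `0 < r0 < r_sat`.
#' @param r_sat Saturation amplitude (normalized units).
#' @return Envelope values, same length as `t_ms`.
#' @export
#' @examples
#' eval_envelope_M(0, a = 20, r0 = 0.1, r_sat = 1)   # = r0
#' eval_envelope_M(1e6, a = 20, r0 = 0.1, r_sat = 1) # -> r_sat
eval_envelope_M <- function(t_ms, a, r0, r_sat) {
  if (!is.finite(a) || a <= 0) {
    abort("`a` must be positive.", class = "gawvot_error_parameter")
  }
  if (!is.finite(r0) || !is.finite(r_sat) || r0 <= 0 || r0 >= r_sat) {
    abort("require 0 < r0 < r_sat for a growing envelope.",
          class = "gawvot_error_parameter")
  }
  xi <- (r0 / r_sat)^2
  r0 / sqrt((1 - xi) * exp(-2 * a * (t_ms / 1000)) + xi)
}

# closed-form time (ms) at which M reaches fraction c of r_sat
m_crossing_time_ms <- function(a, xi, c) {
  -1000 / (2 * a) * log(xi * (1 - c^2) / (c^2 * (1 - xi)))
}

default_m_bounds <- function() {
  list(a = c(1, 1000), r_sat = c(0, 2), r0 = c(0, 1))
}

new_envelope_fit <- function(family, params, fit_peaks, t0_ms,
                             supporting_point = NULL, converged = TRUE,
                             coef_ms = NULL, scale = NULL) {
  fit <- structure(
    list(family = family, params = params, fit_peaks = fit_peaks,
         t0_ms = t0_ms, supporting_point = supporting_point,
         converged = converged, coef_ms = coef_ms, scale = scale,
         rmse = NA_real_),
    class = "envelope_fit"
  )
  fit$rmse <- envelope_rmse(fit, fit_peaks)
  fit
}

#' Fit the Hopf-bifurcation envelope to cycle peaks
#'
#' Fits \eqn{M(t)} to the selected cycle peaks by bounded nonlinear least
#' squares (Levenberg-Marquardt, three deterministic starts for the growth
#' rate). The three variants differ in the number of free parameters:
#' `"a"` optimizes only the growth rate `a` with `r0` and `r_sat` fixed to
#' their measured values; `"as"` additionally frees `r_sat`; `"asr"` frees
#' all of `a`, `r_sat`, `r0`. Free parameters are constrained to physically
#' reasonable ranges: `a` in \[1, 1000\] 1/s, `r_sat` in \[0, 2\], `r0` in
#' \[0, 1\]. The time origin `t = 0` is placed at the first fit peak, where
#' the envelope equals `r0`.
#'
#' @param peaks Selected fit peaks ([select_fit_peaks()]), or any tibble
#'   with `time_ms` and `amplitude`.
#' @param variant `"a"`, `"as"`, or `"asr"`.
#' @param r0 Measured first-cycle amplitude (fixed for variants `"a"` and
#'   `"as"`, initial value for `"asr"`). Defaults to the first peak
#'   amplitude.
#' @param r_sat Measured saturation amplitude (fixed for variant `"a"`,
#'   initial value otherwise).
#' @param bounds Named list of length-2 ranges for `a`, `r_sat`, `r0`.
#' @param a_starts Deterministic multi-start values for `a` (1/s).
#' @return An `envelope_fit` object; see [tidy.envelope_fit()],
#'   [glance.envelope_fit()], [envelope_rmse()], [vot_reciprocal_M()].
#' @export
fit_envelope_M <- function(peaks, variant = c("asr", "as", "a"),
                           r0 = NULL, r_sat = NULL,
                           bounds = default_m_bounds(),
                           a_starts = c(10, 50, 200)) {
  variant <- match.arg(variant)
  if (nrow(peaks) < 3L) {
    abort("need at least 3 peaks to fit the envelope.",
          class = "gawvot_error_insufficient")
  }
  t0 <- peaks$time_ms[1]
  t_rel <- peaks$time_ms - t0
  y <- peaks$amplitude
  if (is.null(r0)) r0 <- y[1]
  if (is.null(r_sat)) r_sat <- max(y)
  eval_m_raw <- function(t_ms, a, r0, r_sat) {
    if (r0 <= 0 || r0 >= r_sat || a <= 0) {
      return(rep(1e6, length(t_ms)))  # infeasible region penalty
    }
    xi <- (r0 / r_sat)^2
    r0 / sqrt((1 - xi) * exp(-2 * a * (t_ms / 1000)) + xi)
  }
  free <- switch(variant, a = "a", as = c("a", "r_sat"),
                 asr = c("a", "r_sat", "r0"))
  lower <- vapply(free, function(p) bounds[[p]][1], numeric(1))
  upper <- vapply(free, function(p) bounds[[p]][2], numeric(1))
  resid_fn <- function(par) {
    p <- list(a = NA_real_, r_sat = r_sat, r0 = r0)
    p[free] <- as.list(par)
    eval_m_raw(t_rel, p$a, p$r0, p$r_sat) - y
  }
  # warm-start the richer variants from the nested simpler fit, so a model
  # with more free parameters can never end up worse than its special case
  starts <- lapply(a_starts, function(a0) {
    c(a = a0, r_sat = r_sat, r0 = min(r0, 0.99 * r_sat))[free]
  })
  if (variant != "a") {
    nested <- tryCatch(
      fit_envelope_M(peaks, variant = if (variant == "asr") "as" else "a",
                     r0 = r0, r_sat = r_sat, bounds = bounds,
                     a_starts = a_starts),
      error = function(e) NULL
    )
    if (!is.null(nested)) {
      warm <- c(a = nested$params$a, r_sat = nested$params$r_sat,
                r0 = min(nested$params$r0, 0.999 * nested$params$r_sat))[free]
      starts <- c(starts, list(warm))
    }
  }
  best <- NULL
  for (start in starts) {
    start <- pmin(pmax(start, lower), upper)
    res <- tryCatch(
      minpack.lm::nls.lm(start, lower = lower, upper = upper, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           ftol = 1e-12, ptol = 1e-12, maxiter = 500)),
      error = function(e) NULL
    )
    if (!is.null(res) && (is.null(best) || res$deviance < best$deviance)) {
      best <- res
    }
  }
  if (is.null(best)) {
    abort("envelope optimization failed for all starts.",
          class = "gawvot_error_fit")
  }
  par <- as.list(coef(best))
  params <- list(a = par$a, r_sat = r_sat, r0 = r0)
  if ("r_sat" %in% free) params$r_sat <- par$r_sat
  if ("r0" %in% free) params$r0 <- par$r0
  new_envelope_fit(
    family = paste0("M_", variant),
    params = params,
    fit_peaks = peaks,
    t0_ms = t0,
    # minpack info codes: 1-4 convergence criteria met, 6-8 no further
    # improvement possible at machine-level tolerances
    converged = best$info %in% c(1:4, 6:8)
  )
}

#' Fit a polynomial envelope with a supporting point
#'
#' Fits a polynomial of order 2, 3 or 4 to the selected cycle peaks by
#' linear least squares, with coefficients unrestricted. A "supporting
#' point" at zero amplitude is placed one oscillation cycle before the
#' first fit peak; it prevents the polynomial from rising towards early
#' times, which would make it miss the lower VOT threshold. Times are
#' centered and scaled to \[-1, 1\] before solving; under-determined
#' systems take the minimum-norm solution (SVD pseudoinverse) so results
#' are reproducible. Coefficients are also reported in the original ms
#' basis (time relative to the first fit peak).
#'
#' @param peaks Selected fit peaks (`time_ms`, `amplitude`).
#' @param order Polynomial order: 2, 3 or 4.
#' @param cycle_period_ms Oscillation period in ms (i.e. `1000 / f0`),
#'   setting the supporting-point offset.
#' @param supporting_point Include the zero-amplitude supporting point?
#'   Default `TRUE`.
#' @return An `envelope_fit` object. The root-mean-square error is computed
#'   over the peaks only; the supporting point never enters the RMSE.
#' @export
fit_envelope_poly <- function(peaks, order, cycle_period_ms,
                              supporting_point = TRUE) {
  order <- as.integer(order)
  if (!order %in% 2:4) {
    abort("`order` must be 2, 3 or 4.", class = "gawvot_error_config")
  }
  t0 <- peaks$time_ms[1]
  t_rel <- peaks$time_ms - t0
  y <- peaks$amplitude
  sp <- NULL
  if (isTRUE(supporting_point)) {
    if (!is.finite(cycle_period_ms) || cycle_period_ms <= 0) {
      abort("`cycle_period_ms` must be positive.", class = "gawvot_error_config")
    }
    sp <- list(time_ms = -cycle_period_ms, amplitude = 0)
    t_fit <- c(sp$time_ms, t_rel)
    y_fit <- c(0, y)
  } else {
    t_fit <- t_rel
    y_fit <- y
  }
  if (length(t_fit) < 3L) {
    abort(sprintf("polynomial fit needs at least 3 points (incl. supporting point); got %d.",
                  length(t_fit)),
          class = "gawvot_error_insufficient")
  }
  if (anyDuplicated(t_fit)) {
    abort("coincident peak times make the polynomial design rank-deficient.",
          class = "gawvot_error_fit")
  }
  # center/scale times to [-1, 1] for conditioning
  t_min <- min(t_fit)
  t_max <- max(t_fit)
  alpha <- 2 / (t_max - t_min)
  beta <- -1 - alpha * t_min
  u <- alpha * t_fit + beta
  X <- outer(u, 0:order, `^`)
  sv <- svd(X)
  tol <- max(dim(X)) * .Machine$double.eps * sv$d[1]
  dinv <- ifelse(sv$d > tol, 1 / sv$d, 0)
  coef_u <- sv$v %*% (dinv * (t(sv$u) %*% y_fit))
  coef_u <- drop(coef_u)
  # back-transform to the original ms basis: p(t) = sum_j c_j (alpha t + beta)^j
  coef_ms <- numeric(order + 1L)
  for (j in 0:order) {
    for (i in 0:j) {
      coef_ms[i + 1L] <- coef_ms[i + 1L] +
        coef_u[j + 1L] * choose(j, i) * alpha^i * beta^(j - i)
    }
  }
  names(coef_ms) <- paste0("a", 0:order)
  new_envelope_fit(
    family = paste0("P", order),
    params = as.list(coef_u),
    fit_peaks = peaks,
    t0_ms = t0,
    supporting_point = sp,
    converged = TRUE,
    coef_ms = coef_ms,
    scale = c(alpha = alpha, beta = beta)
  )
}

#' Evaluate a fitted envelope
#'
#' Evaluates the fitted envelope at times relative to the first fit peak
#' (`t = 0` at the first peak used in the fit, matching the fit's internal
#' time origin).
#'
#' @param object An `envelope_fit`.
#' @param t_ms Times in ms relative to the first fit peak.
#' @param ... Unused.
#' @return Envelope values at `t_ms`.
#' @export
predict.envelope_fit <- function(object, t_ms, ...) {
  if (startsWith(object$family, "M_")) {
    p <- object$params
    eval_envelope_M(t_ms, p$a, p$r0, p$r_sat)
  } else {
    u <- object$scale[["alpha"]] * t_ms + object$scale[["beta"]]
    coef_u <- unlist(object$params)
    y <- rep(coef_u[length(coef_u)], length(u))
    for (j in rev(seq_len(length(coef_u) - 1L))) {
      y <- y * u + coef_u[j]
    }
    y
  }
}

#' Root-mean-square error of an envelope fit
#'
#' RMSE between the fitted envelope and the cycle-peak amplitudes that
#' contributed to the fit. The polynomial supporting point is excluded: it
#' is a constraint device, not data. On normalized signals the value is
#' dimensionless.
#'
#' @param fit An `envelope_fit`.
#' @param peaks Peak tibble (`time_ms`, `amplitude`); defaults to the fit's
#'   own peaks.
#' @param include_supporting_point Also include the polynomial supporting
#'   point, giving the RMS of the residuals the least-squares solver
#'   actually minimized. That quantity is nested across polynomial orders;
#'   the default peak-only RMSE is the reported accuracy measure.
#' @return Nonnegative RMSE.
#' @export
envelope_rmse <- function(fit, peaks = fit$fit_peaks,
                          include_supporting_point = FALSE) {
  if (is.null(peaks) || nrow(peaks) == 0) {
    abort("no peaks to compute the RMSE over.", class = "gawvot_error_input")
  }
  t_rel <- peaks$time_ms - fit$t0_ms
  y <- peaks$amplitude
  if (isTRUE(include_supporting_point) && !is.null(fit$supporting_point)) {
    t_rel <- c(fit$supporting_point$time_ms, t_rel)
    y <- c(fit$supporting_point$amplitude, y)
  }
  sqrt(mean((predict(fit, t_rel) - y)^2))
}

#' @export
print.envelope_fit <- function(x, ...) {
  cat(sprintf("<envelope_fit> %s on %d peaks, rmse = %.4g%s\n",
              x$family, nrow(x$fit_peaks), x$rmse,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Tidy an envelope fit
#'
#' @param x An `envelope_fit`.
#' @param ... Unused.
#' @return For M-family fits, a tibble of `a` (1/s), `r0`, `r_sat`; for
#'   polynomial fits, the coefficients `a0...an` in the ms basis (time
#'   relative to the first fit peak).
#' @export
tidy.envelope_fit <- function(x, ...) {
  if (startsWith(x$family, "M_")) {
    tibble(term = c("a", "r0", "r_sat"),
           estimate = c(x$params$a, x$params$r0, x$params$r_sat))
  } else {
    tibble(term = names(x$coef_ms), estimate = unname(x$coef_ms))
  }
}

#' One-row summary of an envelope fit
#'
#' @param x An `envelope_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `family`, `n_peaks`, `rmse`, `converged`,
#'   `supporting_point`.
#' @export
glance.envelope_fit <- function(x, ...) {
  tibble(
    family = x$family,
    n_peaks = nrow(x$fit_peaks),
    rmse = x$rmse,
    converged = x$converged,
    supporting_point = !is.null(x$supporting_point)
  )
}
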