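test_that("the Hopf envelope anchors at r0, grows monotonically, saturates", {
  expect_equal(eval_envelope_M(0, a = 20, r0 = 0.1, r_sat = 1), 0.1)
  expect_equal(eval_envelope_M(1e7, a = 20, r0 = 0.1, r_sat = 1), 1)
  expect_equal(eval_envelope_M(-1e5, a = 20, r0 = 0.1, r_sat = 1), 0,
               tolerance = 1e-12)

  tt <- seq(-100, 300, by = 0.5)
  m <- eval_envelope_M(tt, a = 35, r0 = 0.07, r_sat = 1.4)
  expect_true(all(diff(m) > 0))
  expect_true(all(m > 0 & m < 1.4))

  # 32.2% -> 67.8% interval from the closed-form crossing times
  dt <- m_time_oracle(20, 0.1, 1, 0.678) - m_time_oracle(20, 0.1, 1, 0.322)
  expect_equal(dt, 49.886, tolerance = 1e-4)
  expect_equal(eval_envelope_M(m_time_oracle(20, 0.1, 1, 0.678), 20, 0.1, 1),
               0.678)

  expect_error(eval_envelope_M(0, a = -1, r0 = 0.1, r_sat = 1),
               class = "gawvot_error_parameter")
  expect_error(eval_envelope_M(0, a = 10, r0 = 1, r_sat = 0.5),
               class = "gawvot_error_parameter")
})

test_that("M fits recover exact parameters from noise-free peaks", {
  pk <- m_peaks(a = 25, r0 = 0.1, r_sat = 1)
  fit_asr <- fit_envelope_M(pk, "asr", r0 = 0.1, r_sat = 1)
  expect_lt(abs(fit_asr$params$a - 25) / 25, 0.01)
  expect_lt(fit_asr$rmse, 1e-6)
  expect_true(fit_asr$converged)

  fit_a <- fit_envelope_M(pk, "a", r0 = 0.1, r_sat = 1)
  expect_lt(abs(fit_a$params$a - 25) / 25, 0.005)

  # fixing r_sat 20% wrong must cost accuracy relative to freeing it
  fit_a_wrong <- fit_envelope_M(pk, "a", r0 = 0.1, r_sat = 1.2)
  expect_gt(fit_a_wrong$rmse, fit_asr$rmse)
})

test_that("freeing parameters never worsens the M-family fit", {
  set.seed(19)
  for (i in 1:10) {
    pk <- m_peaks(a = runif(1, 10, 80), r0 = runif(1, 0.05, 0.3))
    pk$amplitude <- pmax(0.01, pk$amplitude + rnorm(nrow(pk), 0, 0.03))
    r0m <- pk$amplitude[1]
    rsm <- max(pk$amplitude)
    r_a <- fit_envelope_M(pk, "a", r0 = r0m, r_sat = rsm)$rmse
    r_as <- fit_envelope_M(pk, "as", r0 = r0m, r_sat = rsm)$rmse
    r_asr <- fit_envelope_M(pk, "asr", r0 = r0m, r_sat = rsm)$rmse
    expect_lte(r_asr, r_as + 1e-8)
    expect_lte(r_as, r_a + 1e-8)
  }
})

test_that("noisy peak amplitudes still recover the growth rate", {
  set.seed(23)
  rel_err <- replicate(100, {
    pk <- m_peaks(a = 25, r0 = 0.1, r_sat = 1)
    pk$amplitude <- pk$amplitude + rnorm(nrow(pk), 0, 0.02)
    fit <- fit_envelope_M(pk, "asr", r0 = 0.1, r_sat = 1)
    abs(fit$params$a - 25) / 25
  })
  expect_lt(median(rel_err), 0.10)
})

test_that("polynomial fits are exact on consistent data", {
  # amplitudes on t^2 with a consistent supporting point at the origin
  pk <- make_peaks(1:5, (1:5)^2 / 25)
  fit <- fit_envelope_poly(pk, 2, cycle_period_ms = 1)
  expect_lt(fit$rmse, 1e-9)
  # in the shifted basis (t = 0 at first peak): (t+1)^2 / 25
  expect_equal(unname(fit$coef_ms), c(1, 2, 1) / 25, tolerance = 1e-8)
  tt <- seq(-1, 4, by = 0.25)
  expect_equal(predict(fit, tt), (tt + 1)^2 / 25, tolerance = 1e-8)

  # order n through n+1 distinct consistent points interpolates exactly
  for (n in 2:4) {
    tpts <- seq(2, 2 + n * 3, by = 3)
    vals <- 0.1 + 0.2 * seq_len(n + 1)
    pkn <- make_peaks(tpts, vals)
    fitn <- fit_envelope_poly(pkn, n, cycle_period_ms = 2,
                              supporting_point = FALSE)
    expect_lt(fitn$rmse, 1e-9)
  }

  expect_error(fit_envelope_poly(make_peaks(c(1, 1, 3), c(1, 2, 3)), 2, 1),
               class = "gawvot_error_fit")
  expect_error(fit_envelope_poly(make_peaks(1, 1), 3, 1),
               class = "gawvot_error_insufficient")
})

test_that("under-determined polynomial systems resolve reproducibly", {
  pk <- make_peaks(c(4, 9, 14), c(0.2, 0.6, 0.9))
  f1 <- fit_envelope_poly(pk, 4, cycle_period_ms = 5)
  f2 <- fit_envelope_poly(pk, 4, cycle_period_ms = 5)
  expect_lt(f1$rmse, 1e-9)                      # interpolates 4 points
  expect_equal(unlist(f1$params), unlist(f2$params))
  expect_equal(predict(f1, 0), predict(f1, 0))
})

test_that("the supporting point pins the polynomial down at early times", {
  out <- generate_gaw(synthetic_gaw_spec(noise_sd = 0, seed = 5))
  rep_ <- run_pipeline(out$gaw, pipeline_config(variants = "GAW_f",
                                                families = "P4"))
  fp <- rep_$fits[["GAW_f.P4"]]$fit_peaks
  period <- 1000 / rep_$f0
  with_sp <- fit_envelope_poly(fp, 4, period, supporting_point = TRUE)
  without <- fit_envelope_poly(fp, 4, period, supporting_point = FALSE)
  ts <- with_sp$supporting_point$time_ms
  expect_lte(abs(predict(with_sp, ts)), abs(predict(without, ts)))
})

test_that("higher polynomial order never fits the same data worse", {
  set.seed(29)
  for (i in 1:10) {
    pk <- m_peaks(a = runif(1, 15, 60), spacing_ms = 4, t_end_ms = 120)
    pk$amplitude <- pk$amplitude + rnorm(nrow(pk), 0, 0.03)
    # identical data set including the supporting point
    r_full <- function(order) {
      envelope_rmse(fit_envelope_poly(pk, order, 5),
                    include_supporting_point = TRUE)
    }
    expect_lte(r_full(4), r_full(3) + 1e-8)
    expect_lte(r_full(3), r_full(2) + 1e-8)
  }
})

test_that("the reported error is the RMS deviation over the peaks", {
  pk <- m_peaks(a = 30)
  fit <- fit_envelope_M(pk, "a", r0 = 0.1, r_sat = 1)
  expect_lt(envelope_rmse(fit, pk), 1e-6)

  # constant offset: rmse equals the offset magnitude
  shifted <- pk
  shifted$amplitude <- pk$amplitude + 0.04
  expect_equal(envelope_rmse(fit, shifted), 0.04, tolerance = 1e-5)

  # brute-force recomputation on three arbitrary peaks
  pk3 <- make_peaks(c(2, 7, 12), c(0.3, 0.5, 0.4))
  fit3 <- fit_envelope_poly(pk3, 2, 3, supporting_point = TRUE)
  pred <- predict(fit3, pk3$time_ms - fit3$t0_ms)
  expect_equal(fit3$rmse, sqrt(sum((pred - pk3$amplitude)^2) / 3))

  expect_error(envelope_rmse(fit, pk[0, ]), class = "gawvot_error_input")
})

test_that("tidiers expose parameters and fit summaries", {
  pk <- m_peaks()
  fit <- fit_envelope_M(pk, "asr", r0 = 0.1, r_sat = 1)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate"))
  expect_setequal(td$term, c("a", "r0", "r_sat"))
  gl <- glance(fit)
  expect_equal(gl$family, "M_asr")
  expect_true(gl$converged)

  fitp <- fit_envelope_poly(pk, 3, 5)
  expect_equal(tidy(fitp)$term, paste0("a", 0:3))
  expect_true(glance(fitp)$supporting_point)
})
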