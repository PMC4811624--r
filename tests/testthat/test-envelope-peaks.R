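test_that("cycle-peak detection finds one peak per cycle at the antinodes", {
  g <- rectified_sine_gaw(f0 = 200, fps = 8000, n_cycles = 10)
  pk <- detect_cycle_peaks(g, f0 = 200)
  expect_equal(nrow(pk), 10)
  # antinodes at (k + 0.25) periods
  expect_equal(pk$time_ms, (0:9 + 0.25) / 200 * 1000, tolerance = 0.2)
  expect_true(all(pk$preceded_by_closure))

  expect_error(detect_cycle_peaks(gaw_signal(rep(0.5, 100), fps = 8000),
                                  f0 = 200),
               class = "gawvot_error_degenerate")
})

test_that("flat maxima resolve to the earliest sample", {
  # trapezoidal cycles: two equal samples at each crest
  cyc <- c(0, 0.5, 1, 1, 0.5, 0, 0, 0)
  g <- gaw_signal(rep(cyc, 6), fps = 8000)
  pk <- detect_cycle_peaks(g, f0 = 1000)
  crest_first <- which(rep(cyc, 6) == 1)[c(TRUE, FALSE)]
  expect_true(all(pk$index %in% crest_first))
})

test_that("peak series matches generator ground truth on noise-free signals", {
  out <- generate_gaw(synthetic_gaw_spec(noise_sd = 0, seed = 5))
  pk <- detect_cycle_peaks(normalize_gaw(out$gaw), f0 = out$truth$f0)
  expect_equal(nrow(pk), out$truth$n_cycles)
  # envelope grows monotonically up to saturation
  expect_true(all(diff(pk$amplitude[pk$time_ms < 150]) > -1e-9))
  # closure first occurs at the end of cycle n_open_cycles + 1, so the
  # peaks of the first three cycles lack a preceding closure
  expect_equal(pk$preceded_by_closure[1:4], c(FALSE, FALSE, FALSE, TRUE))
})

test_that("first vocal-fold contact is located or reported absent", {
  g <- gaw_signal(c(rep(0.4, 200), 0, rep(0.4, 50)), fps = 8000)
  expect_equal(detect_first_contact(g), 200 / 8000 * 1000)

  expect_true(is.na(detect_first_contact(gaw_signal(rep(0.7, 100), fps = 8000))))

  # trailing zeros without reopening do not count as contact
  g2 <- gaw_signal(c(rep(0.4, 100), rep(0, 20)), fps = 8000)
  expect_true(is.na(detect_first_contact(g2)))

  out <- generate_gaw(synthetic_gaw_spec(n_open_cycles = 2, seed = 6))
  found <- detect_first_contact(normalize_gaw(out$gaw))
  expect_lte(abs(found - out$truth$first_contact_ms), 1000 / 8000 + 1e-9)
})

test_that("the cma averages eligible peaks over a centered kernel", {
  pk <- make_peaks(seq(5, 35, by = 5), rep(0.7, 7))
  expect_equal(central_moving_average(pk)$cma, rep(0.7, 3))

  pk2 <- make_peaks(seq(5, 35, by = 5), c(0.2, 0.4, 0.6, 0.8, 1.0, 1.0, 1.0))
  cma <- central_moving_average(pk2, kernel = 5)
  expect_equal(cma$cma, c(0.60, 0.76, 0.88))
  expect_equal(cma$peak_row, 3:5)

  # two open cycles first: the cma starts centered on the fifth overall peak
  pk3 <- make_peaks(seq(5, 45, by = 5), seq(0.2, 1.0, by = 0.1),
                    closed = c(FALSE, FALSE, rep(TRUE, 7)))
  cma3 <- central_moving_average(pk3, kernel = 5)
  expect_equal(cma3$peak_row[1], 5L)
  expect_equal(cma3$cma[1], mean(pk3$amplitude[3:7]))

  expect_error(central_moving_average(make_peaks(1:4 * 5, rep(1, 4))),
               class = "gawvot_error_insufficient")
})

test_that("cma values are bounded by their window", {
  set.seed(11)
  for (i in 1:20) {
    amps <- runif(9, 0.1, 1.2)
    pk <- make_peaks(1:9 * 5, amps)
    cma <- central_moving_average(pk, kernel = 5)
    for (j in seq_len(nrow(cma))) {
      w <- amps[(j):(j + 4)]
      expect_gte(cma$cma[j], min(w))
      expect_lte(cma$cma[j], max(w))
    }
  }
})

test_that("saturation amplitude is the in-window cma maximum", {
  pk <- make_peaks(seq(5, 35, by = 5), c(0.2, 0.4, 0.6, 0.8, 1.0, 1.0, 1.0),
                   duration_ms = 100)
  sat <- saturation_amplitude(pk, syllable_fraction = 0.4)
  expect_equal(sat$r_sat, 0.88)
  expect_equal(sat$last_fit_peak_row, 7L)

  # monotone-decreasing cma: maximum at the first value
  pkd <- make_peaks(seq(5, 45, by = 5), seq(1.0, 0.2, by = -0.1),
                    duration_ms = 120)
  satd <- saturation_amplitude(pkd, syllable_fraction = 0.4)
  expect_equal(satd$r_sat, central_moving_average(pkd)$cma[1])

  # long plateau: cma bias bounded by envelope curvature
  out <- generate_gaw(synthetic_gaw_spec(noise_sd = 0, seed = 7))
  pkg_ <- detect_cycle_peaks(normalize_gaw(out$gaw), f0 = out$truth$f0)
  satg <- saturation_amplitude(pkg_)
  expect_gte(satg$r_sat, 0.98)
  expect_lte(satg$r_sat, 1.0 + 1e-9)
  expect_lte(satg$r_sat, max(pkg_$amplitude) + 1e-12)

  expect_error(saturation_amplitude(pk, syllable_fraction = 0.01),
               class = "gawvot_error_insufficient")
})

test_that("fit-peak selection applies the variant rules", {
  pk <- make_peaks(1:12 * 5, seq(0.1, 1.2, by = 0.1))
  # contact between peaks 2 and 3
  sel_o <- select_fit_peaks(pk, "unfiltered", first_contact_ms = 12,
                            last_fit_peak_row = 9)
  expect_equal(sel_o$time_ms, 3:9 * 5)
  sel_f <- select_fit_peaks(pk, "filtered", first_contact_ms = 12,
                            last_fit_peak_row = 9)
  expect_equal(sel_f$time_ms, 1:9 * 5)
  # filtered selection is a superset of the unfiltered one
  expect_true(all(sel_o$time_ms %in% sel_f$time_ms))

  expect_error(select_fit_peaks(pk, "unfiltered", first_contact_ms = NA),
               class = "gawvot_error_insufficient")
  expect_error(select_fit_peaks(pk, "unfiltered", first_contact_ms = 12,
                                last_fit_peak_row = 4),
               class = "gawvot_error_insufficient")
})
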