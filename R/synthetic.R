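#' Specification for a synthetic glottal area waveform
#'
#' Defines the study conditions a synthetic onset recording emulates: a
#' nonnegative area oscillation at `f0` whose cycle-peak envelope grows
#' according to the Hopf-bifurcation law [eval_envelope_M()] and then
#' plateaus at the saturation amplitude; the first `n_open_cycles` cycles
#' lack glottal closure (the folds oscillate without touching, so the area
#' never reaches zero), later cycles close fully; additive sample noise and
#' a slow baseline drift mimic segmentation noise and endoscope motion.
#'
#' @param f0 Fundamental frequency in Hz (physiological range 50-500).
#' @param a_true Envelope growth rate in 1/s.
#' @param r0_true First-cycle amplitude (normalized); `0 < r0 < r_sat`.
#' @param r_sat_true Saturation amplitude (normalized).
#' @param n_open_cycles Number of initial cycles without glottal closure.
#' @param duration_ms Total signal duration in ms.
#' @param fps Frame rate in Hz.
#' @param noise_sd Standard deviation of additive Gaussian sample noise.
#' @param drift_amp Amplitude of the slow baseline drift.
#' @param drift_hz Frequency of the baseline drift in Hz.
#' @param second_syllable Append a pause plus a second, larger burst (the
#'   second syllable of a disyllabic utterance)?
#' @param seed Integer seed; a fixed seed yields bit-identical output.
#' @return A validated list of class `synthetic_gaw_spec`.
#' @export
synthetic_gaw_spec <- function(f0 = 200, a_true = 25, r0_true = 0.1,
                               r_sat_true = 1, n_open_cycles = 2,
                               duration_ms = 400, fps = 8000,
                               noise_sd = 0.02, drift_amp = 0, drift_hz = 2,
                               second_syllable = FALSE, seed = 1L) {
  if (f0 < 50 || f0 > 500) {
    abort("`f0` must lie in the physiological range [50, 500] Hz.",
          class = "gawvot_error_config")
  }
  if (r0_true <= 0 || r0_true >= r_sat_true) {
    abort("require 0 < r0_true < r_sat_true.", class = "gawvot_error_config")
  }
  if (a_true <= 0 || duration_ms <= 0 || fps <= 0 || noise_sd < 0) {
    abort("invalid synthetic spec.", class = "gawvot_error_config")
  }
  structure(
    list(f0 = f0, a_true = a_true, r0_true = r0_true, r_sat_true = r_sat_true,
         n_open_cycles = as.integer(n_open_cycles),
         duration_ms = duration_ms, fps = fps, noise_sd = noise_sd,
         drift_amp = drift_amp, drift_hz = drift_hz,
         second_syllable = isTRUE(second_syllable), seed = as.integer(seed)),
    class = "synthetic_gaw_spec"
  )
}

# run code under a fixed seed, restoring the RNG state afterwards
local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# deterministic noise-free burst: envelope E(t) carried by a rectified
# oscillation whose baseline offset ramps down so early cycles stay open
synth_burst <- function(t_s, spec, t_start_s = 0, amp = 1) {
  tl <- t_s - t_start_s
  env <- amp * eval_envelope_M(tl * 1000, spec$a_true, spec$r0_true, spec$r_sat_true)
  off <- 1 + 0.9 * spec$f0 * ((spec$n_open_cycles + 0.5) / spec$f0 - tl)
  off <- pmin(pmax(off, -0.3), 1.5)
  osc <- (sin(2 * pi * spec$f0 * tl) + off) / (1 + off)
  pmax(0, env * osc)
}

#' Generate a synthetic GAW with ground truth
#'
#' Builds the noise-free onset signal from the spec, records the ground
#' truth (true VOT, f0, first-contact time, cycle-peak envelope), then adds
#' seeded noise and drift. All randomness flows through the spec's seed and
#' the caller's RNG state is left untouched.
#'
#' @param spec A [synthetic_gaw_spec()].
#' @return A list with `gaw` (raw [gaw_signal()]) and `truth`, a list
#'   carrying `f0`, `a`, `r0`, `r_sat`, `vot67_crossing_ms` (32.2-67.8%
#'   crossing interval of the true envelope), `vot67_reciprocal_ms`
#'   (`1000/a`), `first_contact_ms`, `peak_times_ms`, `peak_amplitudes`,
#'   and `n_cycles` of the first burst.
#' @export
#' @examples
#' out <- generate_gaw(synthetic_gaw_spec(seed = 42))
#' out$truth$vot67_crossing_ms
generate_gaw <- function(spec) {
  stopifnot(inherits(spec, "synthetic_gaw_spec"))
  n <- round(spec$duration_ms / 1000 * spec$fps)
  t_s <- (seq_len(n) - 1) / spec$fps

  burst1_end_s <- if (spec$second_syllable) 0.45 * spec$duration_ms / 1000 else Inf
  clean <- synth_burst(t_s, spec)
  clean[t_s >= burst1_end_s] <- 0
  if (spec$second_syllable) {
    t2 <- 0.55 * spec$duration_ms / 1000
    sel <- t_s >= t2
    clean[sel] <- synth_burst(t_s[sel], spec, t_start_s = t2, amp = 1.2)
  }

  # ground truth from the noise-free construction
  xi <- (spec$r0_true / spec$r_sat_true)^2
  vot67_cross <- m_crossing_time_ms(spec$a_true, xi, 0.678) -
    m_crossing_time_ms(spec$a_true, xi, 0.322)
  below <- which(clean <= 0)
  first_contact_ms <- NA_real_
  for (i in below) {
    if (i < n && any(clean[(i + 1):n] > 0)) {
      first_contact_ms <- t_s[i] * 1000
      break
    }
  }
  n_cycles <- floor(min(max(t_s), burst1_end_s) * spec$f0 - 0.25) + 1L
  peak_times_ms <- ((seq_len(n_cycles) - 1) + 0.25) / spec$f0 * 1000
  peak_amplitudes <- eval_envelope_M(peak_times_ms, spec$a_true,
                                     spec$r0_true, spec$r_sat_true)

  # segmentation noise scales with the segmented area: peaks near the
  # saturation amplitude carry sd = noise_sd, while a closed glottis stays
  # at exactly zero area (so the no-closure cycles remain detectable)
  noisy <- local_seed(spec$seed, {
    drift <- spec$drift_amp * sin(2 * pi * spec$drift_hz * t_s)
    pmax(0, clean * (1 + stats::rnorm(n, 0, spec$noise_sd)) + drift)
  })

  list(
    gaw = gaw_signal(noisy, fps = spec$fps),
    truth = list(
      f0 = spec$f0, a = spec$a_true, r0 = spec$r0_true,
      r_sat = spec$r_sat_true,
      vot67_crossing_ms = vot67_cross,
      vot67_reciprocal_ms = 1000 / spec$a_true,
      first_contact_ms = first_contact_ms,
      peak_times_ms = peak_times_ms,
      peak_amplitudes = peak_amplitudes,
      n_cycles = n_cycles
    )
  )
}

#' Generate a synthetic high-speed frame stack
#'
#' Renders each GAW sample as a dark elliptical glottis (aspect ratio 1:6,
#' area proportional to the glottal area) on a bright background, with
#' optional multiplicative 50 Hz brightness flicker and an additive
#' high-frequency grid pattern emulating fibre-optic interference. Useful
#' for exercising the image-enhancement front end against a known GAW.
#'
#' @param spec A [synthetic_gaw_spec()]; its GAW drives the per-frame area.
#' @param width,height Frame size in pixels.
#' @param flicker_amp Relative amplitude of the 50 Hz brightness flicker.
#' @param grid_amp Amplitude (grey levels) of the interference grid.
#' @param max_area_frac Glottis area at amplitude 1, as a fraction of the
#'   frame area.
#' @return A list with `frames` (list of intensity matrices in \[0, 255\]),
#'   `fps`, and the driving `gaw`.
#' @export
generate_frames <- function(spec, width = 64, height = 64,
                            flicker_amp = 0.15, grid_amp = 8,
                            max_area_frac = 0.12) {
  out <- generate_gaw(spec)
  vals <- out$gaw$area / max(out$gaw$area)
  t_s <- out$gaw$time_ms / 1000
  cx <- (width + 1) / 2
  cy <- (height + 1) / 2
  xg <- matrix(rep(seq_len(width), each = height), nrow = height)
  yg <- matrix(rep(seq_len(height), times = width), nrow = height)
  grid_pat <- grid_amp * sin(2 * pi * xg / 3) * sin(2 * pi * yg / 3)
  # mild illumination gradient so tissue is never perfectly flat
  background <- 150 + 60 * (yg - 1) / (height - 1)
  frames <- lapply(seq_along(vals), function(i) {
    frame <- background
    area_px <- vals[i] * max_area_frac * width * height
    if (area_px > 0) {
      ax <- sqrt(area_px / (6 * pi))  # semi-minor (x), semi-major = 6 ax (y)
      inside <- ((xg - cx) / ax)^2 + ((yg - cy) / (6 * ax))^2 <= 1
      frame[inside] <- 30
    }
    g <- 1 + flicker_amp * sin(2 * pi * 50 * t_s[i])
    frame <- frame * g + grid_pat
    frame[] <- round_half_up(pmin(pmax(frame, 0), 255))
    frame
  })
  list(frames = frames, fps = spec$fps, gaw = out$gaw)
}
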