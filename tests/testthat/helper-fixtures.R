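# in-code fixtures shared across the suite

# a rectified sinusoid GAW: n_cycles full cycles at f0
rectified_sine_gaw <- function(f0 = 200, fps = 8000, n_cycles = 10, amp = 1) {
  t <- seq(0, n_cycles / f0, by = 1 / fps)
  t <- t[-length(t)]
  gaw_signal(amp * pmax(0, sin(2 * pi * f0 * t)), fps = fps)
}

# wrap bare peak times/amplitudes in the peak-series container
make_peaks <- function(time_ms, amplitude, closed = TRUE,
                       fps = 8000, f0 = 200, duration_ms = max(time_ms) * 2.5,
                       filtered = FALSE) {
  out <- tibble::tibble(
    index = as.integer(round(time_ms / 1000 * fps)) + 1L,
    time_ms = time_ms,
    amplitude = amplitude,
    preceded_by_closure = rep_len(closed, length(time_ms))
  )
  class(out) <- c("gaw_peaks", class(out))
  attr(out, "fps") <- fps
  attr(out, "f0") <- f0
  attr(out, "filtered") <- filtered
  attr(out, "duration_ms") <- duration_ms
  out
}

# closed-form time (ms) at which M(t) reaches fraction c of r_sat;
# independent arithmetic, used as the oracle for crossing computations
m_time_oracle <- function(a, r0, r_sat, c) {
  xi <- (r0 / r_sat)^2
  -1000 / (2 * a) * log(xi * (1 - c^2) / (c^2 * (1 - xi)))
}

# peaks sampled exactly from the Hopf envelope
m_peaks <- function(a = 25, r0 = 0.1, r_sat = 1, spacing_ms = 5, t_end_ms = 200) {
  tt <- seq(0, t_end_ms, by = spacing_ms)
  make_peaks(tt, eval_envelope_M(tt, a, r0, r_sat))
}
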