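---
title: "Measuring voice onset time from glottal area waveforms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring voice onset time from glottal area waveforms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 3.5)
library(gawvot)
library(ggplot2)
```

## The measurement problem

When phonation begins, tracheal airflow sets the adducted vocal folds into
vibration. The oscillation amplitude grows from a small first cycle to a
sustained, roughly periodic state. The duration of this transition — the
voice onset time (VOT) — is a candidate clinical marker of laryngeal
function: a healthy larynx settles into sustained phonation quickly and
consistently, and departures from a narrow physiological VOT range may
indicate functional dysphonia.

High-speed videoendoscopy (HSE) records the vocal folds at thousands of
frames per second. Segmenting the glottis in every frame and stringing the
areas together yields the glottal area waveform (GAW): one area sample per
frame, with maxima at the open glottis and zeros when the folds touch.
`gawvot` turns a GAW into a VOT estimate, and quantifies how trustworthy
that estimate is, using three criteria: *reliability* (how often a VOT can
be computed at all), *consistency* (the spread of the VOT across
recordings), and *accuracy* (how closely the fitted envelope follows the
observed cycle peaks).

## The envelope model

Near oscillation onset the vocal-fold system passes a supercritical Hopf
bifurcation: a stable equilibrium gives way to a limit cycle. The normal
form of that transition implies an amplitude envelope

$$M(t) = r_0\left[(1-\xi)\,e^{-2at} + \xi\right]^{-1/2},
  \qquad \xi = \left(\frac{r_0}{r_\mathrm{sat}}\right)^{2},$$

where $r_0$ is the amplitude of the first oscillation cycle,
$r_\mathrm{sat}$ the saturation amplitude of sustained phonation, and $a$
(1/s) the growth rate. $M$ rises monotonically from $M(0) = r_0$ to
$r_\mathrm{sat}$, and decays to zero for $t \to -\infty$, which is why it
is fitted to the band-pass filtered signal whose offset has been removed.
A useful property is that the time the envelope needs to climb from 32.2%
to 67.8% of $r_\mathrm{sat}$ is

$$\Delta t = \frac{1}{2a}\,
  \ln\!\frac{(1-c_1^2)\,c_2^2}{c_1^2\,(1-c_2^2)} \approx \frac{0.9977}{a},
  \qquad c_1 = 0.322,\; c_2 = 0.678,$$

so $a$ is, to within 0.23%, the reciprocal of that onset time. Three fit
variants differ in their free parameters: `M_a` optimizes only $a$ (with
$r_0$ and $r_\mathrm{sat}$ fixed to their measured values), `M_as` frees
$r_\mathrm{sat}$, `M_asr` frees all three. Free parameters are bounded to
physically reasonable ranges ($a \in [1, 1000]$ 1/s,
$r_\mathrm{sat} \in [0, 2]$, $r_0 \in [0, 1]$) and optimized by bounded
Levenberg–Marquardt least squares on the cycle-peak amplitudes.

As an empirical alternative, polynomials of order 2–4 (`P2`, `P3`, `P4`)
are fitted by linear least squares with unrestricted coefficients. A
*supporting point* of zero amplitude, placed one oscillation cycle before
the first fit peak, keeps the polynomial from rising towards early times;
without it the polynomial often never dips below the lower VOT threshold
and the VOT becomes uncomputable.

## Two VOT definitions

`VOT67` is the time the fitted envelope needs to grow from 32.2% to 67.8%
of the saturation amplitude; `VOT90` from 5% to 90%. For M-family fits
`VOT67` is reported through the reciprocal rule ($1000/a$ ms) and `VOT90`
is not defined. A threshold only counts as reached when the envelope
crosses it *upward from below* inside the search domain; for polynomials
that domain is the fitted data range (supporting point to last fit peak),
because polynomial behaviour beyond the data is extrapolation. Since any
envelope reaching 5% also reaches 32.2%, `VOT90`-computability implies
`VOT67`-computability, and `VOT67` reliability is never lower.

## Pipeline and its tunables

The stages, with defaults and why:

* **Normalization.** The raw GAW (pixel² units) is divided by its maximum
  within the *first syllable*, taken as the first 40% of the signal
  duration (`syllable_fraction = 0.4`) — appropriate for a disyllabic
  utterance whose first syllable carries the onset of interest.
* **Fundamental frequency.** Estimated over the first 180 ms
  (`f0_window_ms`) by autocorrelation of the mean-removed window, with the
  lag search limited to the physiological 50–500 Hz band and parabolic
  interpolation of the autocorrelation peak for sub-sample resolution.
  Estimates on the search boundary raise a warning.
* **Band-pass filtering.** A fourth-order Butterworth band-pass (order 4
  overall, i.e. a second-order prototype) from 0.7 to 1.3 times f0
  removes the DC offset and high-frequency segmentation artifacts. It is
  run forward–backward (zero phase) with odd mirror padding so cycle-peak
  *times* — the quantity VOT is built from — are not displaced by group
  delay.
* **Cycle peaks.** One peak per oscillation cycle: cycles are delimited by
  local minima of a lightly smoothed signal (unfiltered variant) or by
  negative-to-positive zero crossings (filtered variant); flat maxima
  resolve to the earliest sample; peaks below 2% of the signal maximum
  (`min_peak_frac`) are treated as noise.
* **First contact and peak eligibility.** The first sample at or below
  `closure_epsilon = 0.005` (normalized units; true closure gives zero
  area, the margin absorbs segmentation noise) that is later followed by a
  reopening marks the first vocal-fold contact. Peaks not preceded by a
  closure are excluded from the saturation-amplitude estimate, and for
  *unfiltered* fitting only post-contact peaks are used, while *filtered*
  fitting uses all peaks — including the early no-contact cycles, which is
  precisely what the $M$ model's $t \to -\infty$ tail is for.
* **Saturation amplitude.** $r_\mathrm{sat}$ is the maximum of a centered
  moving average of eligible peak amplitudes (kernel of 5 peaks) within
  the first syllable; the last peak of the maximizing window closes the
  fit domain, so sustained-phonation peaks beyond it do not dilute the
  onset fit.
* **Anchoring.** The fit's time origin is the first selected fit peak and
  the measured $r_0$ is that peak's amplitude, so $M(0) = r_0$ anchors at
  the first datum of each variant (for the filtered variant this is the
  first oscillation cycle).

## The synthetic generator

`generate_gaw()` emulates the signal class the analysis assumes: a
nonnegative area oscillation at f0 whose cycle-peak envelope follows
$M(t)$ and then plateaus, with the first `n_open_cycles` cycles oscillating
*without* glottal closure (positive minima) before full closures begin.
The construction multiplies the envelope by
$(\sin 2\pi f_0 t + c(t))/(1 + c(t))$ with an offset ramp $c(t)$ that
starts at 1.5 and falls to $-0.3$, crossing 1 midway through cycle
`n_open_cycles`$+1$: peaks equal the envelope exactly regardless of the
offset, while minima turn from positive to rectified zeros. Ground truth
(true VOT from the closed-form crossings, f0, first-contact time, the peak
envelope) is recorded from the noise-free construction before noise is
added.

Noise is amplitude-proportional — `clean * (1 + N(0, noise_sd))` — so the
standard deviation equals `noise_sd` at the normalized saturation peaks
while a closed glottis stays at exactly zero area. This mirrors how
segmentation error behaves (it scales with the segmented area) and keeps
the no-contact cycles distinguishable from closed ones; purely additive
sample noise of the same magnitude would bury the closure threshold.
A slow additive baseline drift (`drift_amp`, `drift_hz`) emulates
endoscope motion; it is exactly the disturbance the high-pass side of the
band-pass removes. An optional second, louder burst checks that
normalization really uses the *first* syllable.

What the generator does **not** emulate: cycle-to-cycle f0 jitter and
shimmer, amplitude asymmetries between left and right folds, irregular
(aperiodic) pathological onsets, or segmentation dropouts. Passing tests
on synthetic corpora therefore demonstrate correctness of the *method
implementation* under its stated model, not clinical performance on real
recordings.

`generate_frames()` renders each sample as a dark ellipse (1:6 aspect
ratio, area proportional to the GAW) on a gradient background with
multiplicative 50 Hz lamp flicker and an additive interference grid,
exercising the image-enhancement front end: per-frame grey-scale
stretching cancels the flicker, the box filter suppresses the grid, and
clip-and-restretch darkens the glottis relative to tissue.

## Numerical choices

* Threshold crossings are bracketed on a 4001-point grid over the search
  domain and refined by `uniroot` to `1e-4` ms.
* Polynomial systems are solved after centering and scaling times to
  $[-1, 1]$; under-determined systems (few peaks, high order) take the
  SVD minimum-norm solution so results are reproducible; coincident peak
  times are an error. Coefficients are reported in the original ms basis.
* M-family fits use three deterministic growth-rate starts
  ($a \in \{10, 50, 200\}$ 1/s) plus a warm start at the optimum of the
  nested simpler variant; the warm start guarantees that freeing a
  parameter never worsens the fit, making the family's RMSE ordering
  (`M_asr` ≤ `M_as` ≤ `M_a`) hold deterministically.
* The reported RMSE is computed over the contributing cycle peaks only;
  the polynomial supporting point is a constraint device, not data. Note
  that the *least-squares objective* does include the supporting point, so
  only the objective RMSE (`envelope_rmse(..., include_supporting_point =
  TRUE)`) is guaranteed monotone across polynomial orders; the peak-only
  RMSE can deviate from that ordering by a few $10^{-4}$.
* Degenerate inputs fail with classed errors (`gawvot_error_degenerate`,
  `gawvot_error_insufficient`, ...); at corpus level such failures are
  absorbed as non-computable recordings, which is what the reliability
  criterion counts.

## Worked example

```{r example}
out <- generate_gaw(synthetic_gaw_spec(f0 = 200, a_true = 25, seed = 1))
out$truth$vot67_crossing_ms   # ground-truth VOT67 of the envelope

report <- run_pipeline(out$gaw)
report$f0
subset(tidy(report), variant == "GAW_f" & definition == "VOT67")
```

The recommended path — fourth-order polynomial on the band-pass filtered
GAW under the 32.2–67.8% definition — recovers the ground-truth VOT to
within a few percent here. Corpus-level evaluation aggregates such reports:

```{r corpus}
recs <- lapply(1:6, function(s) generate_gaw(synthetic_gaw_spec(seed = s))$gaw)
tab <- evaluate_corpus(recs, pipeline_config(variants = "GAW_f",
                                             families = c("P2", "P4")))
format_corpus_table(tab)
```

```{r plot}
norm <- normalize_gaw(out$gaw)
pk <- detect_cycle_peaks(norm, f0 = report$f0)
autoplot(norm, peaks = pk)
```

## Problem sizes used in the test suite

The shipped tests work on 400 ms signals at 8000 fps (3200 samples, about
80 cycles at 200 Hz), corpora of 10–50 synthetic recordings, 100-replicate
noise studies for parameter recovery, and a 200-point sweep of $(a, \xi)$
for the closed-form identities. These sizes were chosen to pin down each
property with comfortable statistical margin while keeping the full suite
in the tens of seconds.

## Known limitations

* The glottis segmentation step itself (raw frames to areas) is out of
  scope; the trivial thresholding used in tests is plumbing, not a
  segmenter.
* The first syllable is defined as a fixed fraction of the recording, not
  by linguistic segmentation; recordings that start late or cut off early
  will mislocate the saturation window.
* `VOT90`'s 5% lower threshold lies below the first-cycle amplitude of
  many onsets (whenever $r_0 > 0.05\,r_\mathrm{sat}$), so its reliability
  is structurally lower than `VOT67`'s — visibly so on the synthetic
  corpora.
* Voice *offset* analysis and acoustic VOT (the consonant voicing lag of
  phonetics — a different quantity with the same acronym) are not
  implemented.
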