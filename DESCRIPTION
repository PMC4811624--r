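Package: gawvot
Title: Voice Onset Time from Glottal Area Waveforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the voice onset time (VOT) of phonation from glottal
    area waveforms (GAWs) obtained by high-speed laryngeal videoendoscopy.
    Provides image enhancement for raw high-speed frames, GAW normalization,
    fundamental-frequency estimation, zero-phase Butterworth band-pass
    filtering, cycle-peak detection with first-contact annotation, saturation
    amplitude via a central moving average of cycle peaks, envelope fitting
    with a Hopf-bifurcation growth model (one to three free parameters) and
    with polynomials of order two to four anchored by a supporting point,
    VOT under the 32.2-67.8% and 5-90% threshold definitions, and corpus-level
    evaluation of reliability, consistency and accuracy. Includes a seeded
    synthetic GAW and frame-stack generator supplying ground truth for every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
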