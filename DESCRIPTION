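Package: thetaspeech
Title: Sensorimotor Theta Oscillations and Speech Movement Coordination
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for studying how a 6-10 Hz sensorimotor
    theta rhythm coordinates speech movements. Provides a synthetic
    session generator emulating electrocorticography plus vocal-tract
    kinematics, spectral parameterization of periodic and aperiodic
    components, sliding-window phase coherence, Tort modulation-index
    phase-amplitude and phase-movement coupling with circular-shift
    surrogates, articulatory-change pulse analysis and lagged ridge
    (mTRF) encoding models, theta-phase warping of epochs with
    phase-resolved syllable decoding, latency-phase sequence statistics,
    and rhythm periodicity and fluency contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
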