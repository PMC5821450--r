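Package: avigait
Title: Avian Terrestrial Locomotion Mechanics and Prediction for Extinct
    Bipeds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the biomechanical analysis of single-footfall ground
    reaction force (GRF) records from striding bipeds, and a forward model
    that predicts gait from body mass and speed. Provides zero-lag Butterworth
    conditioning, stance detection and impulse-momentum consistency correction
    of force-plate data; a half-range sine-series (Fourier) description of
    body-weight-normalized force-time profiles; whole-stride synthesis of
    centre-of-mass mechanics with percent congruity and net vertical
    displacement; the regression protocol (linear, power and offset-power fits
    with pooled offsets, AIC majority-rules selection and mass modulation of
    coefficients) used to derive speed-scaling laws across bird species; and a
    predictive model that maps body mass, speed and optionally leg length to
    kinematics, sagittal GRF waveforms and centre-of-mass energetics, suitable
    for extrapolation to extinct theropod dinosaurs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    minpack.lm,
    pracma,
    signal,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
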