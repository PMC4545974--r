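Package: artikin
Title: Articulatory Kinematics of Repeated Sentence Productions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of orofacial movement recordings from repeated
    sentence-production tasks: rigid-body head-motion correction of
    optically tracked lip markers, zero-phase low-pass filtering and
    differentiation, segmentation of utterances between opening
    velocity peaks, single-movement and phrase-level kinematic
    measures (displacement and velocity dynamic ranges, durations),
    the lip-aperture variability index quantifying trial-to-trial
    coordination consistency, and group-comparison statistics
    (Levene tests, mixed-design ANOVA, Tukey-Kramer post hocs).
    Includes a minimum-jerk gesture simulator that generates lip
    trajectory ensembles and whole cohorts with known ground truth
    for validating every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    car,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
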