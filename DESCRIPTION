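Package: segwave
Title: Coarse-Grained Dynamical-Module Models of Segmentation and Somitogenesis
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A deterministic, discrete-time simulator of one-dimensional
    segmenting tissues (the arthropod segment-addition zone and the
    vertebrate presomitic mesoderm), built from phenomenological
    "dynamical modules": linear timers, a sinusoidal phase oscillator and
    a multistate fate switch, coupled on a growing row of cells with a
    posterior signalling centre. Implements clock-and-timer models in
    temporal and spatial (positional-information) variants, an
    oscillator-resettable second timer for polarized and pair-rule
    patterns, freeze-readout models with oscillator feedback on
    elongation or maturation, a three-timer model with growth profiles
    and segmentation termination, and a clock-free simultaneous-patterning
    model. Includes analysis metrics (SAZ length, segment lengths, SAZ
    phase difference, recorded-phase distributions, lag scaling,
    pattern equivalence), kymograph rendering, TSV/JSON persistence,
    parameter sweeps and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
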