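Package: rheowave
Title: Resonant Acoustic Rheometry Signal Processing and Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Signal-processing chain for resonant acoustic rheometry (RAR),
    an ultrasound pulse-echo technique that excites and tracks resonant
    surface waves on small liquid or gelling samples to monitor their
    viscoelasticity, e.g. during plasma coagulation. Provides the
    capillary-wave and Rayleigh-wave dispersion relations and their
    inversions to surface tension and shear modulus; a multichannel
    acquisition simulator that synthesises RF A-lines from a programmable
    coagulation trajectory; cross-correlation echo tracking with sub-sample
    parabolic interpolation to recover surface displacement; spectral
    analysis (power spectra, spectrograms, resonant-frequency traces); and
    extraction of coagulation parameters (initial/final frequency, clotting
    start/end times and duration).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    graphics,
    grDevices,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
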