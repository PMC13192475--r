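Package: usdecon
Title: Deconstruction and Reconstruction of Ultrasound Image Degradation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to separate, quantify, and synthetically reconstruct the
    three medium-dependent mechanisms that degrade abdominal B-mode
    ultrasound images: phase aberration, multiple-reverberation clutter, and
    trailing clutter. Provides synthetic acoustic phantom generation
    (layered body wall, sub-resolution scatterers, anechoic lesions, point
    targets), an impedance-preserving map-modulation algebra (isovelocity,
    isoimpedance, and continuous gamma/zeta scaling), a desk-scale 2D linear
    heterogeneous finite-difference acoustic simulator with a curved-array
    source, delay-and-sum beamforming and sector-scan assembly, exact
    clutter subtraction with point-spread-function region statistics,
    quantitative degradation metrics (RMS phase aberration, reverberation
    curves, spatial and lag-one coherence, speckle brightness, lesion
    contrast-to-noise ratio), and post-processing augmentation of RF channel
    data with independently controlled aberration, reverberation, and
    trailing-clutter levels.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
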