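Package: xdn
Title: Radiation-Damage Noise in XFEL Single-Particle Diffraction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates the interaction of a protein-sized particle with a
    femtosecond X-ray free-electron laser pulse and quantifies how radiation
    damage degrades single-particle diffraction. Provides a stochastic
    photoionization and Auger-decay model, a charged-particle surrogate for
    the Coulomb explosion, time-resolved diffraction with ionization-dependent
    Slater-orbital form factors on an Ewald-sphere detector geometry, and the
    ensemble statistics (masked Pearson correlations, resolution-shell
    profiles, speckle contrast, shot/damage/total signal-to-noise ratios and
    diffraction self-gating curves) used to compare damage noise against shot
    noise and sample heterogeneity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    bio3d,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
SystemRequirements: C++17
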