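Package: cosmosdwell
Title: Dwell-Time Kinetics for Colocalization Single-Molecule Spectroscopy
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulation and analysis of multi-wavelength colocalization
    single-molecule spectroscopy (CoSMoS) experiments on macromolecular
    assembly kinetics, with presets for spliceosome activation.  Provides a
    continuous-time Markov (Gillespie) simulator of multi-channel fluorophore
    binding schedules, rendering of noisy integrated-intensity traces with
    optional power-proportional photobleaching, hysteresis threshold event
    detection, coincidence matching and outcome-pathway classification,
    ordering and rebinding analyses, and maximum-likelihood fitting of
    censored exponential-mixture and two-step convolution dwell-time
    densities with bootstrap standard errors, BIC model selection, and a
    two-laser-power global photobleaching control fit.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    graphics,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
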