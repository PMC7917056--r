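Package: abcpattern
Title: Reaction-Diffusion Patterning of the Arabidopsis Floral Meristem
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates a five-gene (LFY, AP1, AG, TFL1, WUSCHEL) reaction-diffusion
    system on a one-dimensional 15-cell transect of the floral meristem L1 layer.
    A WUSCHEL pre-pattern, generated by a boundary-driven repressor subsystem,
    breaks an initially homogeneous state into the A/B/C zones of the ABC model
    of floral organ identity. Provides the kinetic model and its no-flux lattice
    coupling, a fixed-step Euler predictor-corrector (Heun) integrator with
    non-negativity clipping, pattern metrics (zone classification, peak location,
    half-max width, mirror symmetry), scripted in-silico perturbation experiments
    (coupling-coefficient sweeps, TFL1 knockout, WUS-driven exclusion variant,
    parameter robustness scans), configuration file handling, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
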