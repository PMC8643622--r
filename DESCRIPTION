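Package: zmwfccs
Title: Dual-Color PIE-FCCS and FRET Analysis of Fast Biomolecular Binding
    Kinetics in Attoliter Observation Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to simulate and analyse pulsed-interleaved-excitation (PIE)
    dual-color fluorescence cross-correlation spectroscopy (FCCS) experiments on
    reversibly binding, FRET-coupled molecules diffusing through an
    attoliter-scale observation volume, such as zero-mode waveguide measurements
    of DNA G-quadruplex binding by arginine-glycine-rich (RGG) peptides at
    micromolar concentrations.  Includes a Brownian-dynamics photon/trace
    simulator with two-state binding and FRET switching, a multi-tau correlator
    with PIE gating and split-based uncertainties, weighted least-squares fitting
    of triplet/kinetics/diffusion correlation models, amplitude-ratio bound
    fraction estimation, Hill binding-curve fitting, and extraction of
    association and dissociation rate constants, bound-state FRET efficiency and
    association thermodynamics from titration series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
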