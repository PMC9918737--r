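Package: smtweezers
Title: Single-Molecule Magnetic Tweezers Analysis of Nucleosome Mechanics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis toolkit for single-molecule magnetic-tweezers studies
    of nucleosome mechanics. Reconstructs the free-energy cost of unfolding
    the outer DNA wrap from worm-like-chain polymer mechanics, detects
    rupture, dwell and deposition events in force-extension trajectories,
    estimates histone-chaperone dissociation constants by state counting
    over force-jump cycles with bootstrap uncertainty, and calibrates force
    from bead-fluctuation power spectra. Ships seeded trajectory simulators
    (force ramps with Bell-kinetics state transitions, constant-force
    hopping, force-jump binding, deposition steps and calibration bead
    noise) so the full pipeline runs without experimental data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
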