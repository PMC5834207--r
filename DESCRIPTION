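Package: cortisim
Title: Agent-Based Simulation of Plant Cortical Microtubule Self-Organization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Three-dimensional agent-based simulation of interphase plant
    microtubules enclosed in a cell volume. Microtubules are chains of 8 nm
    unit vectors that nucleate on a triangulated cell surface, grow at the
    plus end with directional noise set by a persistence-length parameter,
    treadmill by minus-end shrinkage, and interact by zippering or
    encounter-induced catastrophe. Membrane coupling is either strong
    (growth confined to the local tangent plane) or weak (steep membrane
    encounters trigger catastrophe, shallow ones deflect tangentially), and
    an optional circumferential cue biases growth. The package generates
    rounded-box and ellipsoid cell meshes, advances the network with a
    compiled stepping kernel using spatial hashing, quantifies the array
    (nematic order parameter on a cubic grid, bundled-tubulin fraction,
    membrane distance, orientation histograms), and renders confocal-like
    image stacks and z-projections.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff,
    png
Config/testthat/edition: 3
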