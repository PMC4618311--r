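Package: wallmorph
Title: Quantitative Morphogenesis of Tip-Growing Walled Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the geometry and mechanics of growth domains in
    rod-shaped walled cells such as fission yeast. Provides outline
    tracking and meridional-curvature kymographs, kinematic analysis of
    fiducial (quantum-dot) tracks into wall strain-rate and anisotropy
    profiles, estimation of cell-wall elastic properties (normalized
    Young's modulus E/P and Poisson ratio) from plasmolysis experiments
    via an axisymmetric elastic-shell model, a morphogenetic growth model
    coupling wall incorporation with elastic stretch, and cortical
    fluorescence-profile analysis (full-width at half/95% area, advection
    correction, marker clustering). A synthetic-data module generates
    image stacks, fiducial tracks, fluorescence profiles and
    plasmolysed/turgid contour pairs so the whole pipeline can be
    exercised without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    pracma,
    deSolve,
    jsonlite,
    yaml,
    ape,
    tiff
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
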