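Package: lightSheetSim
Title: Physical-Optics Simulation of Light-Sheet Microscopy Illumination
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Scalar beam-propagation (split-step angular-spectrum) simulation
    of illumination in light-sheet fluorescence microscopy, with decoupled-NA
    elliptical Gaussian pencil beams, refractive sphere phantoms, widefield
    and confocal-line (rolling-shutter slit) detection, and the shadowing and
    contrast statistics used to compare SPIM, mSPIM, DSLM and mDSLM
    architectures. Includes closed-form Gaussian-optics design helpers,
    NA sweep and z-tiling experiment runners, deterministic phantom
    generators, and TIFF/CSV/YAML input-output for reproducible in silico
    illumination studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
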