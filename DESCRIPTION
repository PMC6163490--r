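Package: holovol
Title: Three-Dimensional Lens-Free Holographic Reconstruction by Volumetric
    Deconvolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstruction pipeline for lens-free digital in-line holographic
    microscopy (DIHM). Combines pixel super-resolution from sub-pixel-shifted
    frames, multi-height iterative phase recovery with Sobel-sharpness
    autofocus, angular-spectrum back-propagation into a z-stack, and 3D
    volumetric deconvolution against a simulated point-spread-function volume
    (regularized Wiener inverse and Gold's multiplicative iteration) to
    suppress twin-image and out-of-focus artifacts. Includes a seeded forward
    simulator (beads, bar targets, multi-plane scenes) so every stage is
    testable without experimental data, plus TIFF/CSV/JSON interchange and a
    command-line pipeline driver.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    tools,
    utils,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
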