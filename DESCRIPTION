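Package: agfret
Title: Spillover-Corrected FRET Ratio and Image Quantification for
    Spindle Pole Body Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies sensitized-emission FRET at spindle pole body
    (SPB) puncta from three-channel fluorescence microscopy of
    filamentous fungi.  Single spots are measured per channel by
    cropping, background subtraction, maximum identification and 2D
    Gaussian fitting; spectral spillover (bleed-through) coefficients
    are calibrated from single-label control strains; the ratiometric
    FRET index FRETR is the FRET-channel signal divided by the total
    spillover.  Companion quantifications cover radial colony growth
    area from plate timelapses, needle-spore length morphometry by
    skeletonization, and counting of nuclei carrying an SPB signal.
    A seeded synthetic-microscopy generator with machine-readable
    ground truth produces every input the pipeline consumes, so the
    whole chain is testable end to end without deposited image data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    tiff,
    jsonlite,
    minpack.lm,
    igraph,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
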