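Package: dynpatlak
Title: Whole-Body Patlak Parametric PET Imaging from Two Short Dynamic Acquisitions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for whole-body parametric
    FDG-PET based on Patlak graphical analysis. Provides a closed-form
    irreversible two-tissue-compartment forward model with Feng-type
    arterial input functions, framed dynamic-image simulation for a
    standard 0-75 min protocol and a two-short-dynamic protocol
    (0-6 min + 60-75 min post injection), image-derived input-function
    extraction with model-based bridging of the unsampled 6-60 min
    interval, voxel-wise MR_FDG / DV map generation from the last three
    frames, VOI quantification (41 percent isocontour and fixed-diameter
    spheres, max/mean/peak), and a from-scratch method-comparison battery
    (Passing-Bablok regression with cusum linearity test, Bland-Altman
    limits of agreement, Spearman correlation with confidence intervals).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    minpack.lm,
    RNifti
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
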