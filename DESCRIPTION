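Package: smiauto
Title: Automated Single-Molecule Imaging: Autofocus, Cell Search, Tracking
    and Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computational toolkit for automated in-cell single-molecule
    fluorescence imaging. Provides a synthetic microscopy simulator
    (multi-state and confined 2-D diffusion, Gaussian point-spread-function
    rendering with camera noise, defocused iris stacks, reflection-contrast
    cell scenes, dose-response tables with ground truth), a small
    encoder-decoder neural network with an Adam trainer for coarse autofocus
    classification and cell searching, an iris-edge sharpness autofocus
    score, normalized cross-correlation spot detection with sub-pixel
    Gaussian fitting and frame-to-frame trajectory linking, and
    maximum-likelihood statistics: mean-square displacement, confined
    diffusion fits under normal or log-normal cell-to-cell error models,
    diffusion-state mixtures selected by the Akaike information criterion,
    fluorescence-intensity oligomer-size mixtures, and EC50/IC50
    dose-response pharmacology.
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
    tiff,
    jsonlite,
    minpack.lm,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
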