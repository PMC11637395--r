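Package: eggpale
Title: Flow-Based Abnormal Lesion Emphasis for Chest Radiographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised emphasis of abnormal lesions in chest
    radiographs using an invertible (normalizing-flow) generative model
    trained on normal images only. An input image is mapped to a latent
    code, projected onto the linear subspace spanned by the latent codes
    of the normal training images (the "normal hyperplane"), and pushed
    away from that subspace with a chessboard-distance (L-infinity)
    extrapolation scheme that alters only the latent coordinates
    responsible for the abnormality. Includes the multi-scale coupling
    flow itself (training, exact log-likelihood, singular-value weight
    re-projection), radiograph preprocessing (windowing, geometry
    standardization, bicubic display upsampling), a synthetic chest
    phantom generator with ground-truth nodule masks, and
    contrast-to-noise-ratio based evaluation of enhancement efficacy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    png,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
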