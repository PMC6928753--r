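Package: msplant3d
Title: Multispectral 3D Point-Cloud Phenotyping and Canopy Nutrient Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for nondestructive canopy nutrient (nitrogen, phosphorus,
    potassium) estimation from multispectral 3D point clouds of greenhouse
    plants. Registers multispectral reflectance images onto a depth camera's
    pixel frame by Fourier cross-power-spectrum translation and Fourier-Mellin
    rotation/scale estimation; self-calibrates a turntable rotation axis from
    two colour-sticker observations 180 degrees apart; back-projects RGB-D
    frames to point clouds, rough-registers multiview clouds about the
    calibrated axis and refines them with iterative closest point; scores
    reconstructions with grayscale similarity, spectral overlap and directed
    Hausdorff distance statistics; selects characteristic wavelengths by a
    combined PCA / correlation-coefficient / random-frog procedure; and fits
    back-propagation neural network, support-vector and Gaussian-process
    regressions mapping characteristic-band reflectance to nutrient contents.
    Includes a fully synthetic turntable-scene and spectra generator so the
    whole pipeline is testable without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    RANN,
    e1071,
    jsonlite,
    tiff,
    png,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
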