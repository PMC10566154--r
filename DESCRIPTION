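Package: wheatfvc
Title: Fractional Vegetation Cover of Winter Wheat from Ground, UAS and
    Satellite Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scale-bridging estimation of winter-wheat fractional
    vegetation cover (FVC). Extracts reference cover from RGB ground
    photos by fitting a two-Gaussian mixture to the CIE L*a*b* a*-channel
    histogram, bridges the gap between centimetre-scale UAS multispectral
    orthomosaics and 10 m satellite reflectance by cubic-convolution
    downscaling and zonal-mean upscaling onto a common 2 m grid, derives
    wall-to-wall cover labels with random-forest, support-vector, NDVI
    pixel-dichotomy and half-Gaussian models, and trains a small
    Levenberg-Marquardt backpropagation network mapping satellite
    reflectance to cover. Includes a seeded synthetic scene generator
    (spatially correlated cover fields, linear vegetation/soil spectral
    mixing, two-Gaussian photo rendering) so the whole workflow is
    reproducible and testable without field data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    png,
    jsonlite,
    minpack.lm,
    randomForest,
    e1071
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
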