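Package: riceCanopy
Title: Measurement, 3D Reconstruction and Virtual Clipping of Rice Canopy
    Architecture
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A technique system for extracting rice plant architecture from
    calibrated leaf and tiller photographs, assembling the measurements into a
    3D digital plant architecture, and extracting canopy traits with the
    virtual blade (virtual clipping) method: vertical, cylindrical and voxel
    leaf-area density profiles, leaf azimuth and inclination distributions,
    and within-canopy light interception. Includes a parametric synthetic
    canopy generator and image renderers so the whole pipeline can be
    exercised end-to-end without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    MASS,
    grDevices,
    png,
    stats,
    utils,
    yaml
Suggests:
    ggplot2,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
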