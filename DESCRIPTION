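Package: canopytraits
Title: Canopy Trait Extraction and Abiotic Stress Monitoring for Field
    Phenotyping Platforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns raw sensor observations from gantry-based field phenotyping
    platforms into canopy traits and stress indicators. Computes green cover
    fraction from RGB microplot images, inverts multi-angle gap fractions to
    Green Area Index and Average Leaf Angle under a Poisson turbid-medium model
    with an ellipsoidal leaf angle distribution, derives NDVI, MTCI and MCARI2
    from calibrated spectroradiometer scans, estimates crop height from LiDAR
    point clouds, analyses trait time series (area under the curve, stress
    onset), and runs a daily soil water bucket budget with tensiometer-threshold
    irrigation triggering. Ships seeded synthetic-scene generators so the whole
    pipeline is testable end-to-end without field data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    e1071,
    grDevices,
    jsonlite,
    minpack.lm,
    multcomp,
    png,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
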