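Package: fundusHSI
Title: Hyperspectral Conversion and Spectral Screening of Color Fundus Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for hyperspectral screening of color fundus
    photographs for hydroxychloroquine (HCQ) retinopathy. Generates synthetic
    per-pixel reflectance scenes with known ground truth, renders them through a
    colorimetric camera model, calibrates and applies an RGB-to-401-band
    spectral reconstruction (380-780 nm), samples five anatomical regions of
    interest (F, S1, S2, I1, I2), compares group mean spectra with contiguous
    band-window selection, reproduces band-selected color images, and trains a
    compact convolutional classifier with Grad-CAM localization. Includes the
    cohort summary statistics (two-sample t, chi-square with continuity
    correction, one-way ANOVA from summaries) used for case-control tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
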