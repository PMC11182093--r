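Package: retmap
Title: Multimodal Retinal Image Mapping and Photoreceptor Mosaic Quantification
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Builds a common micrometre-scale coordinate frame across
    adaptive-optics scanning light ophthalmoscope (AOSLO), infrared
    reflectance, autofluorescence and optical coherence tomography (OCT)
    images of the human retina. Provides schematic-eye retinal
    magnification from ocular biometry, desinusoiding of resonant-scanner
    distortion calibrated with a Ronchi ruling, strip-based normalized
    cross-correlation frame registration and averaging, landmark-based
    multimodal alignment and montaging anchored at the foveal center,
    Voronoi-tessellation cone and retinal pigment epithelium mosaic
    metrics with bounded-cell edge correction, detection of confocal
    versus split-detection discordance (dark cones), OCT layer
    segmentation with retinal and outer-retinal thickness extraction,
    normative z-score statistics with exact Wilcoxon rank-sum tests and
    intraclass correlation, and seeded phantom generators with known
    ground truth for validating every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
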