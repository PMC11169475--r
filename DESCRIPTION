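Package: descspim
Title: Computational Toolkit for Desktop Light-Sheet Microscopy of Cleared Tissue
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-processing and acquisition-geometry toolkit for simple
    desktop selective plane illumination microscopes (SPIM) used with tissue
    clearing media. Provides closed-form acquisition optics (refractive focal
    path, synchronous stage speed correction, z-stack planning), movie-to-stack
    assembly, flat-field correction from dye-solution references, tiling
    light-sheet fusion with focus-contrast seam detection, Gaussian-beam and
    point-spread-function metrology (focal FWHM, Rayleigh length, effective
    field of view), registration quality metrics (normalized mutual
    information, zero-mean normalized cross-correlation, integer z-shift
    estimation), vessel-to-drug distance quantification on binarized channel
    pairs, and Beer-Lambert virtual hematoxylin-eosin rendering. A synthetic
    phantom generator with machine-readable ground truth exercises every
    pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    tiff,
    jsonlite,
    minpack.lm,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
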