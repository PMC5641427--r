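Package: spermshape
Title: Elliptic Fourier Morphometrics of Sperm Head Contours
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Outline-based geometric morphometrics for nucleus-stained sperm
    head images. Implements Otsu discriminant-analysis binarization,
    Moore-neighbor boundary tracing to Freeman chain codes, elliptic Fourier
    descriptor (EFD) estimation and first-harmonic normalization, PCA of the
    normalized coefficient space with a two-pass PC1-score abnormality filter,
    per-head morphological indicators (aspect ratio, antero-posterior axis,
    head area), and group-comparison statistics including an all-pairs
    Steel-Dwass test. A synthetic shape and image generator produces
    hook-shaped head populations with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    EBImage,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
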