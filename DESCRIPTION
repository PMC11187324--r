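Package: wsiscreen
Title: Whole-Slide Image Screening with Ensembles of Multiple-Instance
    Learners
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Toolkit for weakly supervised screening of haematoxylin and
    eosin stained whole-slide images: overlapping multi-magnification
    tiling, four-stage tile quality control (background standard-deviation,
    pen-mark, purple-to-pink ratio and Otsu tissue-presence filters),
    Reinhard-style stain normalisation, multiple-instance learning with
    optional gated attention pooling, and majority-vote ensemble
    classification with an explicit indecision (abstention) outcome.
    Includes a synthetic histology generator so the full pipeline can be
    exercised and validated end to end without clinical slides.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
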