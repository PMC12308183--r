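Package: RepeatGeometry
Title: Geometrical Descriptors of Structured Tandem Repeat Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes per-unit geometrical descriptors of structured tandem
    repeat proteins (STRPs) from a 3D structure and repeat-unit boundary
    annotations. Curvature is obtained by sliding-window circle fitting of
    unit centroids refined with a widest-crown criterion; twist (roll) and
    pitch are obtained by canonically re-orienting consecutive units in
    circle-derived local frames, superposing them by least squares, and
    decomposing the resulting rotation into Tait-Bryan angles. Includes a
    synthetic solenoid generator with known ground-truth angles, batch
    processing over many structures, CSV output and axis-visualization
    export.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    parallel,
    jsonlite,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
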