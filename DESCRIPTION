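Package: fsmi
Title: Antibody Microarray Cross-Reactivity Graphs and Deconvolution of
    Multiplex Sandwich Immunoassays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing fluorescence sandwich microarray
    immunoassays (FSMI) built from panels of polyclonal antibodies, such as
    biosensor chips for detecting perchlorate-reducing bacteria in
    environmental samples. Quantifies replicate spot intensities into
    per-antibody fluorescence profiles with background estimation and
    positivity calls; builds the antibody cross-reactivity matrix G from
    one-immunogen-at-a-time panel assays and the associated directed
    antibody graph; deconvolutes multiplex fluorescence profiles by solving
    F = G F' and classifies every antibody into presence codes
    (I, II.a, II.b, III) that separate cognate detections from
    cross-reactions and off-array relatives; estimates limits of detection
    from serial-dilution calibration curves; and generates seedable
    synthetic assay data with Langmuir binding and lognormal spot noise for
    validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
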