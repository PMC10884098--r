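Package: axiscope
Title: Axial Regional Identity and Stochastic Coexpression in Neural Stem Cell Lines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for three linked analyses of early central nervous system
    regionalisation: grid-averaged migration vector fields estimated from
    time-lapse epiblast cell trajectories; a Hox-code classifier that assigns
    anteroposterior regional coverage (forebrain through caudal spinal cord)
    to bulk expression profiles, with a dorsoventral coherence check; and a
    stochastic-independence model of transcription-factor coexpression in
    single cells, fitted by through-origin regression of observed against
    predicted (product-of-marginals) coexpression frequencies, with a
    read-depth stratified inflation diagnostic. A synthetic-data module
    generates single-cell count matrices with per-cell capture depth,
    tiered bulk expression profiles, and planar cell trajectories so that
    every stage of the pipeline can be exercised and calibrated offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    methods,
    stats,
    utils,
    graphics,
    grDevices
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
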