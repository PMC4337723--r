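Package: shearsetpoint
Title: Shear-Stress Set-Point Analysis for Gradient Flow-Chamber Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models the wall shear-stress field of a tapered (gradient)
    parallel-plate flow chamber, quantifies endothelial nuclear orientation
    and transcription-factor nuclear translocation from two-channel
    fluorescence micrographs, maps measurements to local shear magnitude,
    and estimates the biphasic response optimum (the shear-stress "set
    point"). Includes a ground-truthed synthetic-image generator emulating
    sheared endothelial monolayers so that every stage of the pipeline is
    testable without microscopy data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    tibble,
    dplyr,
    rlang,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
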